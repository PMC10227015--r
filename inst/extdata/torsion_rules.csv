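class,windows,description
sp3_sp3,40:80;160:200;280:320,staggered rotamers (gauche+/anti/gauche-) with 20 degree slack
biaryl,20:160;200:340,aryl-aryl twist away from the coplanar clash
aryl_amide,0:40;140:220;320:360,near-planar anilide/benzamide torsions
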