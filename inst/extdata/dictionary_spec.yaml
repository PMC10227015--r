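# Default generic modification dictionary.
#
# The design space is the cross-product of
#   ring cores x decoration positions x C/O/N spacers   plus
#   functional groups x C/O/N spacers,
# deduplicated by canonical fragment SMILES. Every fragment carries exactly
# one attachment dummy atom [*]. Ring cores are written with the dummy
# first and the ring atoms in cyclic order, so relative decoration
# positions (ortho/meta/para on 6-membered rings; adjacent/non-adjacent
# mapped to the same labels on smaller rings) are well defined.
#
# This file is the explicit, editable reconstruction of a "manually
# designed" medicinal-chemistry modification dictionary: common functional
# groups, carbocyclic and 1-2-heteroatom N/O rings of sizes 3-6, and
# spacers of length 0-2 over {C, O, N}. Chemically hopeless combinations
# are not suppressed at generation time; the enumeration stage drops
# fragments that cannot form a valence-valid molecule and the filtering
# stage handles liabilities (peroxides, hydrazines, ...) via alerts.
version: 1
decoration_group: C        # substituent placed on decorated ring positions
spacers:
  lengths: [0, 1, 2]
  atoms: ["C", "O", "N"]
functional_groups:
  - {id: methyl,            smiles: "[*]C"}
  - {id: ethyl,             smiles: "[*]CC"}
  - {id: isopropyl,         smiles: "[*]C(C)C"}
  - {id: tert_butyl,        smiles: "[*]C(C)(C)C"}
  - {id: vinyl,             smiles: "[*]C=C"}
  - {id: trifluoromethyl,   smiles: "[*]C(F)(F)F"}
  - {id: difluoromethyl,    smiles: "[*]C(F)F"}
  - {id: fluoro,            smiles: "[*]F"}
  - {id: chloro,            smiles: "[*]Cl"}
  - {id: bromo,             smiles: "[*]Br"}
  - {id: hydroxy,           smiles: "[*]O"}
  - {id: methoxy,           smiles: "[*]OC"}
  - {id: ethoxy,            smiles: "[*]OCC"}
  - {id: trifluoromethoxy,  smiles: "[*]OC(F)(F)F"}
  - {id: amino,             smiles: "[*]N"}
  - {id: methylamino,       smiles: "[*]NC"}
  - {id: dimethylamino,     smiles: "[*]N(C)C"}
  - {id: cyano,             smiles: "[*]C#N"}
  - {id: cyanomethyl,       smiles: "[*]CC#N"}
  - {id: carbamoyl,         smiles: "[*]C(N)=O"}
  - {id: n_methylcarbamoyl, smiles: "[*]C(=O)NC"}
  - {id: acetamido,         smiles: "[*]NC(C)=O"}
  - {id: carboxyl,          smiles: "[*]C(O)=O"}
  - {id: methoxycarbonyl,   smiles: "[*]C(=O)OC"}
  - {id: acetyl,            smiles: "[*]C(C)=O"}
  - {id: formyl,            smiles: "[*]C=O"}
  - {id: methylsulfonyl,    smiles: "[*]S(C)(=O)=O"}
  - {id: sulfamoyl,         smiles: "[*]S(N)(=O)=O"}
  - {id: methylsulfanyl,    smiles: "[*]SC"}
  - {id: hydroxymethyl,     smiles: "[*]CO"}
  - {id: aminomethyl,       smiles: "[*]CN"}
  - {id: methoxymethyl,     smiles: "[*]COC"}
rings:
  # size 3: only the adjacent position exists -> ortho
  - {id: cyclopropyl,   size: 3, smiles: "[*]C1CC1",      decorations: [none, ortho]}
  - {id: oxiranyl,      size: 3, smiles: "[*]C1CO1",      decorations: [none, ortho]}
  - {id: aziridinyl,    size: 3, smiles: "[*]C1CN1",      decorations: [none, ortho]}
  # size 4-5: adjacent -> ortho, first non-adjacent -> meta
  - {id: cyclobutyl,    size: 4, smiles: "[*]C1CCC1",     decorations: [none, ortho, meta]}
  - {id: oxetanyl,      size: 4, smiles: "[*]C1COC1",     decorations: [none, ortho, meta]}
  - {id: azetidinyl,    size: 4, smiles: "[*]C1CNC1",     decorations: [none, ortho, meta]}
  - {id: cyclopentyl,   size: 5, smiles: "[*]C1CCCC1",    decorations: [none, ortho, meta]}
  - {id: thf_2_yl,      size: 5, smiles: "[*]C1CCCO1",    decorations: [none, ortho, meta]}
  - {id: pyrrolidin_2_yl, size: 5, smiles: "[*]C1CCCN1",  decorations: [none, ortho, meta]}
  - {id: pyrrolidin_1_yl, size: 5, smiles: "[*]N1CCCC1",  decorations: [none, ortho, meta]}
  - {id: furan_2_yl,    size: 5, smiles: "[*]c1ccco1",    decorations: [none, ortho, meta]}
  - {id: pyrrol_2_yl,   size: 5, smiles: "[*]c1ccc[nH]1", decorations: [none, ortho, meta]}
  - {id: imidazol_2_yl, size: 5, smiles: "[*]c1ncc[nH]1", decorations: [none, ortho, meta]}
  - {id: oxazol_2_yl,   size: 5, smiles: "[*]c1ncco1",    decorations: [none, ortho, meta]}
  - {id: pyrazol_3_yl,  size: 5, smiles: "[*]c1cc[nH]n1", decorations: [none, ortho, meta]}
  # size 6: ortho/meta/para
  - {id: cyclohexyl,    size: 6, smiles: "[*]C1CCCCC1",   decorations: [none, ortho, meta, para]}
  - {id: phenyl,        size: 6, smiles: "[*]c1ccccc1",   decorations: [none, ortho, meta, para]}
  - {id: thp_2_yl,      size: 6, smiles: "[*]C1CCCCO1",   decorations: [none, ortho, meta, para]}
  - {id: piperidin_1_yl, size: 6, smiles: "[*]N1CCCCC1",  decorations: [none, ortho, meta, para]}
  - {id: piperazin_1_yl, size: 6, smiles: "[*]N1CCNCC1",  decorations: [none, ortho, meta, para]}
  - {id: morpholin_4_yl, size: 6, smiles: "[*]N1CCOCC1",  decorations: [none, ortho, meta, para]}
  - {id: pyridin_2_yl,  size: 6, smiles: "[*]c1ccccn1",   decorations: [none, ortho, meta, para]}
  - {id: pyridin_3_yl,  size: 6, smiles: "[*]c1cccnc1",   decorations: [none, ortho, meta, para]}
  - {id: pyridin_4_yl,  size: 6, smiles: "[*]c1ccncc1",   decorations: [none, ortho, meta, para]}
  - {id: pyrimidin_2_yl, size: 6, smiles: "[*]c1ncccn1",  decorations: [none, ortho, meta, para]}
  - {id: pyrazin_2_yl,  size: 6, smiles: "[*]c1cnccn1",   decorations: [none, ortho, meta, para]}
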