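{
  "comment": "Default pharmacophore feature definitions: SMARTS pattern per feature type with a geometry rule (point, vector, group, ring). This table is a documented, replaceable default; it is not a reconstruction of any proprietary feature set. centroid_atoms (1-based positions within the match) restricts the atoms used for group centroids.",
  "entries": [
    {"type": "D", "smarts": "[#7;!H0;!$([#7-])]", "geometry": "vector",
     "comment": "N-H donor; one feature per attached hydrogen when explicit hydrogens are present"},
    {"type": "D", "smarts": "[#8;!H0;!$([#8-])]", "geometry": "vector",
     "comment": "O-H donor"},
    {"type": "A", "smarts": "[OX1]", "geometry": "vector",
     "comment": "carbonyl / oxide oxygen acceptor; direction along the idealized lone-pair bisector"},
    {"type": "A", "smarts": "[OX2;!$([OX2][!#6]);!$([o])]", "geometry": "vector",
     "comment": "hydroxyl / ether oxygen acceptor"},
    {"type": "A", "smarts": "[NX2;!$([N+])]", "geometry": "vector",
     "comment": "sp2 nitrogen lone-pair acceptor (imines, azo)"},
    {"type": "A", "smarts": "[nX2]", "geometry": "vector",
     "comment": "pyridine-type aromatic nitrogen"},
    {"type": "A", "smarts": "[NX1]", "geometry": "vector",
     "comment": "nitrile nitrogen"},
    {"type": "N", "smarts": "[CX3](=[OX1])[O-]", "geometry": "group",
     "centroid_atoms": [2, 3],
     "comment": "carboxylate: one negative feature at the centroid of the two oxygens"},
    {"type": "N", "smarts": "[O-;!$([O-][#6X3]=[OX1])]", "geometry": "point",
     "comment": "other deprotonated oxygens (phenolate, phosphate...)"},
    {"type": "N", "smarts": "[S-]", "geometry": "point",
     "comment": "thiolate"},
    {"type": "P", "smarts": "[N+;!$([N+][O-])]", "geometry": "point",
     "comment": "protonated amine / quaternary nitrogen (nitro excluded)"},
    {"type": "P", "smarts": "[n+]", "geometry": "point",
     "comment": "protonated aromatic nitrogen"},
    {"type": "H", "smarts": "[#6;!$([#6]~[#7,#8,#15,#16]);!$([#6][F,Cl,Br,I])]",
     "geometry": "group",
     "comment": "apolar carbon; bonded matches are clustered into contiguous hydrophobic groups placed at their centroid"},
    {"type": "R", "smarts": "a1aaaaa1", "geometry": "ring",
     "comment": "six-membered aromatic ring; feature at the ring centroid, direction normal to the ring plane"},
    {"type": "R", "smarts": "a1aaaa1", "geometry": "ring",
     "comment": "five-membered aromatic ring"}
  ]
}
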