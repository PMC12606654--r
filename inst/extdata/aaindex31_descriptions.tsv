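KYTJ820101	Hydropathy index (Kyte-Doolittle, 1982)
HOPT810101	Hydrophilicity value (Hopp-Woods, 1981)
EISD840101	Consensus normalized hydrophobicity scale (Eisenberg, 1984)
FAUJ830101	Hydrophobic parameter pi (Fauchere-Pliska, 1983)
ZIMJ680101	Hydrophobicity (Zimmerman et al., 1968)
PONP800101	Surrounding hydrophobicity in folded form (Ponnuswamy et al., 1980)
ARGP820101	Hydrophobicity index (Argos et al., 1982)
JANJ780101	Average accessible surface area (Janin et al., 1978)
WOLR810101	Hydration potential (Wolfenden et al., 1981)
GRAR740102	Polarity (Grantham, 1974)
RADA880108	Mean polarity (Radzicka-Wolfenden, 1988)
CIDH920105	Normalized average hydrophobicity scales (Cid et al., 1992)
ZIMJ680104	Isoelectric point (Zimmerman et al., 1968)
KLEP840101	Net charge (Klein et al., 1984)
FAUJ880111	Positive charge (Fauchere et al., 1988)
FAUJ880112	Negative charge (Fauchere et al., 1988)
CHAM830107	A parameter of charge transfer capability (Charton-Charton, 1983)
BIGC670101	Residue volume (Bigelow, 1967)
CHOC750101	Average volume of buried residue (Chothia, 1975)
FAUJ880103	Normalized van der Waals volume (Fauchere et al., 1988)
CHAM820101	Polarizability parameter (Charton-Charton, 1982)
DAWD720101	Size (Dawson, 1972)
TSAJ990101	Volumes including the crystallographic waters using the ProtOr (Tsai et al., 1999)
CHOP780201	Normalized frequency of alpha-helix (Chou-Fasman, 1978b)
CHOP780202	Normalized frequency of beta-sheet (Chou-Fasman, 1978b)
CHOP780203	Normalized frequency of beta-turn (Chou-Fasman, 1978b)
LEVM780101	Normalized frequency of alpha-helix, with weights (Levitt, 1978)
JANJ780102	Percentage of buried residues (Janin et al., 1978)
BHAR880101	Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
VINM940101	Normalized flexibility parameters (B-values), average (Vihinen et al., 1994)
CHOC760101	Residue accessible surface area in tripeptide (Chothia, 1976)
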