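low_cm,high_cm,compound,description,notes
1728,1746,hemicellulose/acetylated xylan,C=O stretch of acetyl and carboxyl groups,esterified lignins may contribute
1708,1727,hemicellulose/acetylated xylan,C=O stretch (shifted carbonyl),
1692,1700,protein,Amide I shoulder,tentative
1640,1660,protein,Amide I: C=O stretch,water bending may overlap
1648,1676,lignin,C=O stretch in conjugated p-substituted aryl ketones,
1590,1598,lignin,aromatic skeletal vibration,
1548,1556,protein,Amide II: N-H deformation + C-N stretch,
1504,1510,lignin,aromatic skeletal vibration,G > S
1512,1518,lignin,aromatic skeletal vibration,G > S
1458,1464,cellulose,CH2 of pyran ring symmetric scissoring; OH and CH deformation,lignin and xylan contribute
1422,1430,crystalline cellulose,CH2 symmetric bending,hemicelluloses and lignins contribute
1368,1376,cellulose,CH deformation vibration and CH bending,hemicelluloses contribute
1355,1365,cellulose,CH bending,
1340,1348,cellulose,CH wagging,
1330,1338,crystalline cellulose,O-H in-plane bending,lignin S ring plus G ring condensed at 1330-1324
1312,1320,crystalline cellulose,CH2 rocking vibration,
1276,1284,cellulose,CH2 wagging,
1244,1250,lignin,stretching of phenolics,
1230,1240,hemicellulose/acetylated xylan,acetyl and carboxyl vibration; C-C and C-O and C=O stretch,lignins contribute
1196,1206,cellulose,OH in-plane deformation,
1154,1164,cellulose,C-O-C asymmetric stretch,
1116,1136,cellulose,C-O-C glycosidic vibration,hemicelluloses contribute
1095,1105,pectin,C-O stretch of galacturonan backbone,tentative
1048,1058,cellulose,C-O valence vibration mainly from C3-O3H,
1028,1038,cellulose,C-O valence vibration,lignin aromatic C-H in-plane deformation; G > S
985,996,cellulose,C-O valence vibration,
915,925,lignin,aromatic C-H out-of-plane deformation,
894,902,cellulose,C1-H deformation of amorphous cellulose,
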