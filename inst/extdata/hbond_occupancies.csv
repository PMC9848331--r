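variant,chain1,resno1,resname1,chain2,resno2,resname2,class,wt_occupancy,mut_occupancy,note
K303N,A,303,LYS,A,401,ILE,direct,0.99,0.99,side chain to backbone N of I401
K303N,A,303,LYS,A,398,ASP,salt_bridge,0.55,0.00,charge-assisted bond lost with shorter N303 side chain
N373S,A,373,ASN,A,322,GLY,water_mediated,0.30,0.30,transient bridge kept in the mutant
D375N,A,375,ASP,A,378,ASP,direct,0.90,0.88,backbone O to backbone N of D378
D375N,A,375,ASP,A,377,ALA,direct,0.55,0.52,side chain to backbone NH of A377
D375H,A,375,ASP,A,378,ASP,direct,0.90,0.85,backbone O to backbone N of D378
D375H,A,375,ASP,A,377,ALA,direct,0.55,0.80,imidazole N of H375 to backbone NH of A377
E399K,A,399,GLU,A,396,CYS,direct,0.60,0.60,backbone-backbone bond kept
E399K,A,399,GLU,A,376,LYS,salt_bridge,0.70,0.00,ionic anchor of the interface loop lost
T390I,A,390,THR,B,332,LYS,direct,0.80,0.45,inter-monomer bond weakened below half occupancy
T390I,A,390,THR,A,406,GLU,direct,1.00,0.75,side-chain bond to E406 lost; backbone bond weakened
V407A,A,407,VAL,B,407,VAL,hydrophobic_contact,0.95,0.85,inter-monomer packing only
T400S,A,400,THR,A,396,CYS,direct,0.80,0.80,kept by S400
T400S,A,400,THR,A,398,ASP,direct,0.80,0.80,kept by S400
W402S,A,402,TRP,A,404,GLU,direct,0.75,0.45,indole NH bridge to E404 destabilised
W402S,A,402,TRP,A,394,ILE,direct,0.75,0.75,backbone-backbone bonds kept
W402S,B,307,SER,A,404,GLU,direct,0.90,0.10,context: inter-monomer bond lost downstream of the mutation
N301S,A,301,ASN,A,299,TYR,water_mediated,0.30,0.30,transient bridge kept in the mutant
S307F,A,307,SER,B,404,GLU,direct,0.90,0.00,inter-monomer bond to E404B lost
S307F,B,402,TRP,B,404,GLU,direct,0.75,0.10,context: neighbouring bond destabilised
V384F,A,384,VAL,A,323,PHE,hydrophobic_contact,0.90,0.95,packing with F323 improved by the bulkier side chain
V384F,A,384,VAL,A,386,LEU,hydrophobic_contact,0.90,0.85,packing with L386
T306I,A,306,THR,A,403,LEU,direct,1.00,0.00,hydroxyl bond to backbone O of L403 lost
T306I,A,306,THR,A,368,TYR,direct,0.55,0.00,hydroxyl bond to Y368 lost
T306I,A,306,THR,A,307,SER,direct,0.55,0.00,hydroxyl bond to backbone NH of S307 lost
T306I,A,306,THR,A,287,VAL,direct,0.90,0.60,backbone-backbone pair weakened by the bulky I306
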