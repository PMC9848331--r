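variant,structural,interaction,conpath,class
K303N,-,+,+,MHPPV
N373S,-,-,-,LPPV
D375N,-,-,-,LPPV
D375H,-,-,-,LPPV
E399K,-,+,-,MLPPV
T390I,-,+,+,MHPPV
V407A,-,-,+,MLPPV
T400S,-,-,-,LPPV
W402S,-,+,+,MHPPV
N301S,+,-,-,MLPPV
S307F,+,+,+,HPPV
V384F,+,-,+,MHPPV
T306I,+,+,+,HPPV
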