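gene	signal	evidence
SLC2A5	fruit-sugar	encodes GLUT5, the major intestinal fructose transporter with exclusive affinity for fructose (fruit sugar)
ABCG5	plant-sterol	encodes sterolin-1, which eliminates plant sterols; plant sterols are mainly present in nuts and seeds
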