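name	file	resname	terminal_protons
glycerol	glycerol.pdb	GOL	HO1,HO3
xylitol	xylitol.pdb	XLT	HO1,HO5
d-xylulose	d-xylulose.pdb	XUL	HO1
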