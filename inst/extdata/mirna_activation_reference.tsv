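tissue	name	z	state	p_value
BAT	miR-9-5p	-2.40	Inhibited	2.35e-04
BAT	miR-16-5p	-2.19	Inhibited	7.06e-05
Liver	miR-9-5p	-4.01	Inhibited	5.41e-13
Liver	miR-1	-2.93	Inhibited	2.91e-02
Liver	miR-127-3p	-2.00	Inhibited	1.54e-03
Liver	miR-299a-3p	-2.00	Inhibited	8.56e-04
Liver	miR-344d-3p	-2.00	Inhibited	8.56e-04
Liver	miR-379-5p	-2.00	Inhibited	2.00e-03
Liver	miR-381-3p	-2.00	Inhibited	3.18e-03
Liver	miR-409-3p	-2.00	Inhibited	6.09e-04
Liver	miR-411-5p	-2.00	Inhibited	8.56e-04
Liver	miR-431-5p	-2.00	Inhibited	8.56e-04
Liver	miR-433-3p	-2.00	Inhibited	2.00e-03
Liver	miR-494-3p	-2.00	Inhibited	4.76e-03
Liver	miR-495-3p	-2.00	Inhibited	2.00e-03
Liver	miR-541-5p	-2.00	Inhibited	4.18e-04
Liver	miR-543-3p	-2.00	Inhibited	1.16e-03
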