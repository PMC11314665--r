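name	category	roles	rationale
Stairs	1	context	Context to higher variability and asymmetry measures
Doorway	1	context	Doorways can provoke freezing of gait in some people with Parkinson's
Shower	1	context	Context to the type of room
Sink	1	context	Context to the type of room
Toilet	1	context	Context to the type of room
Table	1	context	Context to higher gait variability and asymmetry characteristics; can also provoke freezing of gait
Bed	1	context	Context to the type of room
Signage	1	context	Fluctuations in gait signal may be due to pausing to read signage
Vehicle	1	context	Context to the type of environment
Chair	2	context,fall_risk	Potential tripping hazard due to obstruction
Animal	2	context,fall_risk	Potential tripping hazard with animals running between/in front of the wearer
Wet surface	2	context,fall_risk	Potential hazard due to slippery surface
Matt/rug/carpet	3	fall_risk	Potential tripping hazard due to change in surface friction and/or curled/folded edge
Obstacle	3	fall_risk	Generic catch-all for potential obstructions
Raised kerb	3	fall_risk	Tripping hazard
Person	4	context,privacy	Detected person will be blurred, but may also evoke gait alteration when navigating around them
Screen	4	privacy	Detection of any screen (e.g. laptop/TV/phone) will be blurred
Book	4	privacy	Catch-all for any text-based document that will be blurred
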