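genus	bougainville	eastern_highlands	east_sepik
Ageratum	2	1	1
Alpinia	7	5	4
Alstonia	4	3	4
Aristolochia	1	1	2
Barringtonia	2	1	1
Ficus	11	7	11
Graptophyllum	1	1	1
Hemigraphis	1	2	1
Leucosyke	1	1	1
Litsea	1	1	2
Melastoma	1	2	1
Mucuna	3	1	5
Musa	2	1	2
Piper	4	5	6
Plectranthus	2	1	6
Psidium	2	1	2
Sida	1	1	1
Smilax	1	3	1
Syzygium	4	4	4
Uncaria	2	1	2
Zingiber	1	2	4
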