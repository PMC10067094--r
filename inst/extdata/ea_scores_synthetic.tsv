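ref	pos	alt	score
R	110	L	55.0
R	110	P	60.2
R	158	L	82.4
R	158	H	79.0
R	175	H	91.5
R	175	C	88.8
R	213	Q	58.3
Y	220	C	67.9
Y	220	S	62.5
Y	236	C	88.1
G	245	S	84.0
R	248	Q	89.0
R	248	W	90.2
R	249	S	86.7
R	273	C	78.8
R	273	H	80.1
R	273	L	83.4
R	280	K	71.3
R	282	W	93.2
R	282	Q	76.1
E	285	K	74.9
R	337	H	41.6
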