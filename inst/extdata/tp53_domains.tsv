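name	start	end
TAD	1	42
PRR	61	94
DBD	102	292
L2	163	195
L3	236	251
TET	323	356
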