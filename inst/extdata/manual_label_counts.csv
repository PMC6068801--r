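class,samples,duration
SITTING,395004,56:01:51
WALKING,169908,26:09:26
RUNNING,8250,01:20:09
CYCLING,19132,02:40:35
TRANSPORTATION,75244,11:47:21
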