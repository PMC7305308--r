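id	chain	class	nt_len	anchor_pos
IGHV1-S	IGH	V	288	93
IGHV2-S	IGH	V	288	93
IGHV3-S	IGH	V	288	93
IGHV4-S	IGH	V	288	93
IGHV5-S	IGH	V	288	93
IGHV6-S	IGH	V	288	93
IGHV7-S	IGH	V	288	93
IGHV8-S	IGH	V	288	93
IGHD1-S	IGH	D	19	NA
IGHD2-S	IGH	D	13	NA
IGHD3-S	IGH	D	21	NA
IGHD4-S	IGH	D	17	NA
IGHD5-S	IGH	D	15	NA
IGHD6-S	IGH	D	20	NA
IGHJ1-S	IGH	J	48	2
IGHJ2-S	IGH	J	48	2
IGHJ3-S	IGH	J	48	2
IGHJ4-S	IGH	J	48	2
IGKV1-S	IGK	V	288	93
IGKV2-S	IGK	V	288	93
IGKV3-S	IGK	V	288	93
IGKV4-S	IGK	V	288	93
IGKV5-S	IGK	V	288	93
IGKV6-S	IGK	V	288	93
IGKV7-S	IGK	V	288	93
IGKV8-S	IGK	V	288	93
IGKJ1-S	IGK	J	48	2
IGKJ2-S	IGK	J	48	2
IGKJ3-S	IGK	J	48	2
IGKJ4-S	IGK	J	48	2
IGLV1-S	IGL	V	288	93
IGLV2-S	IGL	V	288	93
IGLV3-S	IGL	V	288	93
IGLV4-S	IGL	V	288	93
IGLV5-S	IGL	V	288	93
IGLV6-S	IGL	V	288	93
IGLV7-S	IGL	V	288	93
IGLV8-S	IGL	V	288	93
IGLJ1-S	IGL	J	48	2
IGLJ2-S	IGL	J	48	2
IGLJ3-S	IGL	J	48	2
IGLJ4-S	IGL	J	48	2
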