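alias	canonical
b-actin	Actb
beta-actin	Actb
actb	Actb
b-tubulin	Tubb
beta-tubulin	Tubb
tubb	Tubb
a-tubulin	Tuba
alpha-tubulin	Tuba
tuba	Tuba
gapdh	Gapdh
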