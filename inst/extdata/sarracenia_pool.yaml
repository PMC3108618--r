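mosquito: consumer
midge: consumer
mite: consumer
copepod: consumer
rotifer: consumer
protozoa1: consumer
protozoa2: consumer
protozoa3: consumer
protozoa4: consumer
bacteria: basal
detritus: basal
pom: basal
yeast: basal
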