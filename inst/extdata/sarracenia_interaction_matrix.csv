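taxon,mosquito,midge,mite,copepod,rotifer,protozoa1,protozoa2,protozoa3,protozoa4,bacteria,detritus,pom,yeast
mosquito,0,0,0,0,1,1,1,1,1,0,0,0,0
midge,0,0,0,0,0,0,0,0,0,0,1,1,0
mite,0,0,0,0,0,0,0,0,0,1,1,1,0
copepod,0,0,0,0,1,1,1,1,1,0,0,0,0
rotifer,1,0,0,1,0,0,0,0,0,1,0,0,1
protozoa1,1,0,0,1,0,0,0,0,0,1,0,0,1
protozoa2,1,0,0,1,0,0,0,0,0,1,0,0,1
protozoa3,1,0,0,1,0,0,0,0,0,1,0,0,1
protozoa4,1,0,0,1,0,0,0,0,0,1,0,0,1
bacteria,0,0,1,0,1,1,1,1,1,0,1,1,1
detritus,0,1,1,0,0,0,0,0,0,1,0,0,0
pom,0,1,1,0,0,0,0,0,0,1,0,0,0
yeast,0,0,0,0,1,1,1,1,1,1,0,0,0
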