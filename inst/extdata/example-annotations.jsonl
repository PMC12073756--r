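{"cubeId":"demo-cube","class":"brown_a","colMin":10,"rowMin":18,"colMax":70,"rowMax":60}
{"cubeId":"demo-cube","class":"grey","colMin":2,"rowMin":2,"colMax":158,"rowMax":10}
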