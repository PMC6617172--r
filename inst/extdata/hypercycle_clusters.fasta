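>alpha count=1
AAGGAGGGGGGGGGGGGGAGGGAAGGGAAVGGGGG
>beta count=1
EGAAGGGGGGAGGGGVGGGVAGGGGDGGAGGGGAGAGGGA
>chi count=1
GAAEGGVGGDGVAGGGGVGGVAAGAGAGGAGGAVAGGG
>delta count=1
AAGGAGAGAGGGGGVGGAGGGVGGAGAGGGGGAGGGG
>epsilon count=1
AGGAAGGEAGGGGAEGEAGAGAGG
>phi count=1
GEGEAGAGAGGGAAAGGGGAAGAGVADGGGGAGAAGAGGGAVDGVGAAGGGGG
>gamma count=1
GEAGGSGAAGGGGGAVGGGGVEGGGEGGGGGGGGGGAGGGG
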