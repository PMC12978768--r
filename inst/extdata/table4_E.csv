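"aj","parameter_number","E"
"a1",13,0.721
"a2",17,0.863
"a3",19,0.909
"a4",59,0.892
"a5",84,0.711
"a6",96,0.965
"a7",101,0.907
"a8",121,0.624
"a9",149,0.964
"a10",199,0.847
"a11",202,0.756
"a12",204,0.665
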