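"aj","parameter_number","parameter_name","kappa"
"a1",13,"Mulliken charge of N2 atom",-17.633
"a2",17,"Mulliken charge of C13 atom",10.552
"a3",19,"Mulliken charge of O3 atom",0.354
"a4",59,"Polarizability ZYY",-0.001
"a5",84,"Perpendicular distance of O3 to the C1-H9-C9 plane",1.13
"a6",96,"Angle between the C1-H9-C9 plane and the O3-C11 line",0.172
"a7",101,"Angle between the C1-H9-C9 plane and the O3-C10 line",-0.347
"a8",121,"Angle H9-N1-N2",1.274
"a9",149,"Logarithm of the O3-N1 distance",-0.327
"a10",199,"Polar surface area",-0.004
"a11",202,"Relative energy (aqueous)",0.001
"a12",204,"Torsion angle O3-O2-C5-C7",0.001
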