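metric,direction,threshold,matching_percent,type1_percent
ptit,unimpaired,3,89,3.6
ptit,unimpaired,4,79,1.1
ptit,unimpaired,5,69,0.5
ptit,unimpaired,6,54,0.1
ptit,unimpaired,7,42,0.0
tpi,unimpaired,0.50,80,2.3
tpi,unimpaired,0.70,70,0.8
tpi,unimpaired,0.90,49,0.4
tpi,unimpaired,0.95,39,0.1
tpi,unimpaired,0.98,28,0.0
ptit,impaired,3,58,11.0
ptit,impaired,4,35,4.6
ptit,impaired,5,16,1.5
ptit,impaired,6,5,0.5
ptit,impaired,7,2,0.1
tpi,impaired,0.50,54,3.2
tpi,impaired,0.70,44,1.8
tpi,impaired,0.90,26,0.7
tpi,impaired,0.95,17,0.3
tpi,impaired,0.98,8,0.1
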