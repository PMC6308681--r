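time_ms,tilt_deg
0,21.5
50,18.0
100,14.0
150,10.5
200,7.0
250,3.5
300,0.0
350,-3.5
400,-7.0
450,-10.5
500,-14.0
550,-18.0
600,-21.5
650,-25.0
700,0.5
750,-0.5
800,5.0
850,-5.0
900,12.0
950,-12.0
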