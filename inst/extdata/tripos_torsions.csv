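a,b,V,n,s
C.3,C.3,2.0,3,1
C.3,N.3,1.6,3,1
C.3,N.4,1.6,3,1
C.3,O.3,1.2,3,1
C.3,S.3,1.0,3,1
C.3,C.2,0.3,6,-1
C.3,C.ar,0.3,6,-1
C.3,N.2,0.6,6,-1
C.2,C.2,12.0,2,-1
C.2,N.2,12.0,2,-1
C.2,N.3,6.0,2,-1
C.2,O.3,6.0,2,-1
C.ar,N.3,1.0,2,-1
C.ar,O.3,1.0,2,-1
C.ar,C.ar,2.0,2,-1
C.ar,C.2,1.0,2,-1
C.ar,N.2,1.0,2,-1
C.ar,S.3,1.0,2,-1
C.ar,C.1,0,1,-1
C.3,C.1,0,1,-1
C.2,C.1,0,1,-1
N.3,N.3,1.0,3,1
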