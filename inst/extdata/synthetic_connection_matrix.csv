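"","C1","C2","C3","C4","C5","C6","C7","C8","C9","C10","C11","C12","R"
"C1","","","","","{s1:0.5, s2:0.5}","","","","","","","","{s2:0.6, s3:0.4}"
"C2","","","","","{s1:0.6, s2:0.4}","","","","","","","","{s1:0.5, s2:0.5}"
"C3","","{s1:0.5, s2:0.5}","","","","{s1:0.5, s2:0.5}","","","","","","","{s2:0.5, s3:0.5}"
"C4","","","","","","{s1:0.6, s2:0.4}","","","","","","","{s-2:0.55, s-1:0.45}"
"C5","","","{s1:0.5, s2:0.5}","","","","{s1:0.5, s2:0.5}","","","","","","{s2:0.6, s3:0.4}"
"C6","","","","","","","","","","","","","{s1:0.6, s2:0.4}"
"C7","","","","","","","","","","","","","{s1:0.5, s2:0.5}"
"C8","{s1:0.55, s2:0.45}","","","","","","{s1:0.6, s2:0.4}","","","","{s1:0.6, s2:0.4}","{s1:0.5, s2:0.5}","{s1:0.7, s2:0.3}"
"C9","","","{s1:0.7, s2:0.3}","","","","","{s1:0.6, s2:0.4}","","","","","{s2:0.5, s3:0.5}"
"C10","{s1:0.4, s2:0.6}","","{s1:0.5, s2:0.5}","{s-2:0.6, s-1:0.4}","","{s1:0.5, s2:0.5}","","{s1:0.5, s2:0.5}","{s2:0.7, s3:0.3}","","","","{s2:0.4, s3:0.6}"
"C11","","{s-2:0.6, s-1:0.4}","","","{s-2:0.5, s-1:0.5}","","","","","","","","{s-2:0.5, s-1:0.5}"
"C12","","","","","{s2:0.6, s3:0.4}","","","","","","","","{s2:0.55, s3:0.45}"
"R","","","{s1:0.6, s2:0.4}","","{s1:0.5, s2:0.5}","","","","","{s1:0.7, s2:0.3}","","{s1:0.6, s2:0.4}",""
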