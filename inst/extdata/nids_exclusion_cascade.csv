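initial_n,excluded_single_wave,excluded_nonresponse,excluded_missing,final_n
28237,9340,447,420,18030
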