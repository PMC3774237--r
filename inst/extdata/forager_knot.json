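{"c_mg_s": 5, "q_mg_s": 0.1, "y_req_mg_s": 0.2, "gizzard_g": 10}
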