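{"n_players":2,"action_counts":[2,2],"payoffs":[["3","0","5","1"],["3","5","0","1"]],"signals":"perfect","W":"perfect"}
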