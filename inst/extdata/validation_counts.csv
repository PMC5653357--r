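stage,tp,fp,fn
code_screen,103,70,5
full_pipeline,97,5,9
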