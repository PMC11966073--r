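kind,category,count
TF,DS-disease,164
TF,DS-drug,309
TF_total,Total,473
MCQ,DS-disease,123
MCQ,DS-drug,206
MCQ_total,Total,329
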