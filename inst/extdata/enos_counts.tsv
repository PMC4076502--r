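snp	case_AA	case_Aa	case_aa	ctrl_AA	ctrl_Aa	ctrl_aa
eNOS_-786T>C	167	200	54	203	185	35
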