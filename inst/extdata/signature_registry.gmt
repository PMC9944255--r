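CAF_SIGNATURE	CAF	COL1A1	COL1A2	COL3A1
EMT_Carretero_2010	EMT	USER_MUST_SUPPLY
IPRES_Hugo_2016	EMT	USER_MUST_SUPPLY
PATHWAY_Carretero_2010	EMT	USER_MUST_SUPPLY
EMT_STROMA_Wang_2018	EMT	USER_MUST_SUPPLY
GENERIC_EMT_MES_Tan_2014	EMT	USER_MUST_SUPPLY
HALLMARK_EMT	EMT	USER_MUST_SUPPLY
PAN_EMT_Mak_2016	EMT	USER_MUST_SUPPLY
GENERIC_EMT_EPI_Tan_2014	EMT_EPI	USER_MUST_SUPPLY
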