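exam_id,series_id,obscured_pct,model_category
E00001,E00001_S1,,optimal
E00002,E00002_S1,20,moderate
E00003,E00003_S1,,mild
E00004,E00004_S1,,moderate
E00005,E00005_S1,,optimal
E00006,E00006_S1,,optimal
E00007,E00007_S1,20,moderate
E00008,E00008_S1,,mild
E00009,E00009_S1,,mild
E00010,E00010_S1,,optimal
E00011,E00011_S1,,optimal
E00012,E00012_S1,,optimal
E00012,E00012_S2,,optimal
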