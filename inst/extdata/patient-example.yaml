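# Worked-example patient: a 35-year-old male at the 2013-02-15 panel date.
patient_id: P001
sex: male
birth_date: 1977-06-02
registered: 2012-11-01
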