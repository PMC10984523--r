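procedure_type,period_start,period_kind,relative_change
screening,2020,year,-0.063
screening,2021,year,-0.051
diagnostic_procedure,2020,year,-0.117
diagnostic_procedure,2021,year,-0.034
treatment,2020,year,0.001
treatment,2021,year,-0.072
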