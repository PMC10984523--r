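procedure_type,period_start,period_kind,relative_change
screening,2020,year,-0.40
diagnosis,2020,year,-0.102
diagnosis,2021,year,-0.005
surgery,2020,year,-0.051
surgery,2021,year,0.024
radiotherapy,2020,year,0.015
radiotherapy,2021,year,0.215
chemotherapy,2020,year,0.039
chemotherapy,2021,year,0.147
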