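!Series_title	"Synthetic series-matrix fixture (constructed for parser tests; not real GEO data)"
!Series_geo_accession	"GSE00000"
!Sample_geo_accession	"GSM000001"	"GSM000002"
!Sample_title	"line A, well watered"	"line A, drought"
!Sample_characteristics_ch1	"genotype: A"	"genotype: A"
!Sample_characteristics_ch1	"treatment: well watered"	"treatment: drought"
!series_matrix_table_begin
"ID_REF"	"GSM000001"	"GSM000002"
"248352_at"	9.125	7.25
"247723_at"	8.5	6.875
"249052_at"	5.0	5.125
"262347_at"	7.75	7.0
!series_matrix_table_end
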