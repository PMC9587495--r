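"profile","create_record","record_clinical_data","match_concepts","update_data","analyze","visualize","export"
"service","true","true","true","true","true","true","true"
"facility","false","false","false","true","true","true","true"
"district","false","false","false","true","true","true","true"
"region","false","false","false","true","true","true","true"
"country","false","false","false","true","true","true","true"
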