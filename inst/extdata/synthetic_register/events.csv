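"compartment_id","event_type","year","removed_volume_m3_ha","treated_area_ha"
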