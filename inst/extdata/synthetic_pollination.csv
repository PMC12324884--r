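,Pollinator_01,Pollinator_02,Pollinator_03,Pollinator_04,Pollinator_05,Pollinator_06,Pollinator_07,Pollinator_08,Pollinator_09,Pollinator_10
Plant_01,0,0,0,0,0,0,1,1,0,1
Plant_02,0,0,1,0,0,0,0,0,0,1
Plant_03,1,0,1,0,0,1,1,0,1,0
Plant_04,0,0,1,0,0,0,0,0,0,0
Plant_05,0,0,0,1,1,1,0,0,1,1
Plant_06,1,0,0,0,0,0,1,0,0,0
Plant_07,0,0,1,1,0,0,0,0,0,0
Plant_08,0,1,0,0,0,0,0,1,1,1
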