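item_id,item_label,count0,count1,countNA
item_01,Purpose completely evident,175,525,0
item_02,"Common, everyday language",183,517,0
item_03,Medical terms defined,241,459,0
item_04,Active voice,174,526,0
item_05,Chunks information into short sections,548,143,9
item_06,Informative headers,601,90,9
item_07,Logical sequence,164,536,0
item_08,Provides a summary,458,233,9
item_09,Text on screen easy to read,137,294,269
item_10,Words heard clearly,97,539,64
item_11,Clear illustrations and photographs,111,338,251
item_12,Simple tables with clear headings,192,57,451
overall,Understandability,315,385,0
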