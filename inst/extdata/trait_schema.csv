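trait,kind,label,score,state,cohorts,diag_cohorts
primary_covert_pattern,plumage,Primary covert pattern,0,Buff edged (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
primary_covert_pattern,plumage,Primary covert pattern,1,Plain/Solid (Hybrid/MALL),MI;MA;FI;FA,MI;MA;FI;FA
lesser_covert_pattern,plumage,Lesser covert pattern,0,Buff edged (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
lesser_covert_pattern,plumage,Lesser covert pattern,1,Plain/Solid (MALL),MI;MA;FI;FA,MI;MA;FI;FA
greater_covert_pattern,plumage,Greater coverts pattern,0,Buffy or part white across coverts (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
greater_covert_pattern,plumage,Greater coverts pattern,1,Complete white across coverts (Hybrid/MALL),MI;MA;FI;FA,MI;MA;FI;FA
speculum_color,plumage,Speculum color,0,Green (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
speculum_color,plumage,Speculum color,1,No green (Hybrid/MALL),MI;MA;FI;FA,MI;MA;FI;FA
percent_green_head,plumage,Percent green in head,0,No green (MEDU),MI;MA,MI;MA
percent_green_head,plumage,Percent green in head,1,1-25% green,MI;MA,MI;MA
percent_green_head,plumage,Percent green in head,2,26-50% green,MI;MA,MI;MA
percent_green_head,plumage,Percent green in head,3,> 50% green (MALL),MI;MA,MI;MA
face_neck_pattern,plumage,Overall face and neck,0,Slightly patterned (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
face_neck_pattern,plumage,Overall face and neck,1,Continuously strong pattern (Hybrid/MALL),MI;MA;FI;FA,MI;MA;FI;FA
black_spots_bill,plumage,Black spots around bill,0,Absent (MEDU),MI;MA,MI;MA
black_spots_bill,plumage,Black spots around bill,1,Present (MALL),MI;MA,MI;MA
back_pattern,plumage,Overall back feather pattern & color,0,Chevron patterned or buff/brown edges (MEDU),MI;MA;FI,MI;MA;FI
back_pattern,plumage,Overall back feather pattern & color,1,Solid or light patterned (MALL),MI;MA;FI,MI;MA;FI
scapular_pattern,plumage,Scapular pattern,0,Chevron patterned or buff/brown edges (MEDU),MI;MA;FI,MI;MA;FI
scapular_pattern,plumage,Scapular pattern,1,Solid or light patterned (MALL),MI;MA;FI,MI;MA;FI
rump_pattern,plumage,Rump,0,Brown w/ buffy chevrons & buffy edges (MEDU),MI;MA;FI,MI;MA;FI
rump_pattern,plumage,Rump,1,Black w/ rufous chevrons w/ rufous edges (Hybrid),MI;MA;FI,MI;MA;FI
rump_pattern,plumage,Rump,2,Solid black (MALL),MI;MA;FI,MI;MA;FI
outer_tail_edges,plumage,Outer two tail feathers (color of outer edges),0,Buff edged (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
outer_tail_edges,plumage,Outer two tail feathers (color of outer edges),1,White edged (MALL),MI;MA;FI;FA,MI;MA;FI;FA
central_tail_curl,plumage,Central tail feather curl,0,Not raised (MEDU),MI;MA,MI;MA
central_tail_curl,plumage,Central tail feather curl,1,Slightly raised (partial curl),MI;MA,MI;MA
central_tail_curl,plumage,Central tail feather curl,2,> Half curl (MALL),MI;MA,MI;MA
breast_pattern,plumage,Breast feather pattern & color,0,Strong internal pattern (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
breast_pattern,plumage,Breast feather pattern & color,1,Slight internal pattern w/ whitish edges (MALL),MI;MA;FI;FA,MI;MA;FI;FA
breast_belly_pattern,plumage,Overall breast & belly feather pattern,0,Uniform (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
breast_belly_pattern,plumage,Overall breast & belly feather pattern,1,Breast & belly different color (MALL),MI;MA;FI;FA,MI;MA;FI;FA
flank_pattern,plumage,Flank feather pattern,0,Chevron patterned (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
flank_pattern,plumage,Flank feather pattern,1,Slight internal marking (MALL),MI;MA;FI;FA,MI;MA;FI;FA
undertail_covert_pattern,plumage,Under-tail covert pattern,0,Chevron patterned (MEDU),MI;MA;FI;FA,MI;MA;FI;FA
undertail_covert_pattern,plumage,Under-tail covert pattern,1,Spotted to subtle internal marking (Hybrid),MI;MA;FI;FA,MI;MA;FI;FA
undertail_covert_pattern,plumage,Under-tail covert pattern,2,Gray-black or unpatterned (MALL),MI;MA;FI;FA,MI;MA;FI;FA
bill_length,structural,Bill length,NA,NA,MI;MA;FI;FA,
bill_width,structural,Bill width,NA,NA,MI;MA;FI;FA,
central_tail_length,structural,Central tail feathers length,NA,NA,MI;MA;FI;FA,
culmen_nares,structural,Culmen-nares,NA,NA,MI;MA;FI;FA,
tarsus_length,structural,Tarsus length,NA,NA,MI;MA;FI;FA,FI;FA;MA
wing_arc,structural,Wing arc,NA,NA,MI;MA;FI;FA,MA
mass,mass,Mass,NA,NA,MI;MA;FI;FA,MA;FA
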