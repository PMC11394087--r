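"stomach_id","category","rank","group","count","volume_ml"
"S01","Coleoptera","order","invertebrate",1,0.388888888888889
"S02","Coleoptera","order","invertebrate",1,0.388888888888889
"S03","Coleoptera","order","invertebrate",1,0.388888888888889
"S04","Coleoptera","order","invertebrate",1,0.388888888888889
"S05","Coleoptera","order","invertebrate",1,0.388888888888889
"S06","Coleoptera","order","invertebrate",1,0.388888888888889
"S07","Coleoptera","order","invertebrate",1,0.388888888888889
"S08","Coleoptera","order","invertebrate",1,0.388888888888889
"S09","Coleoptera","order","invertebrate",1,0.388888888888889
"S10","Hemiptera","order","invertebrate",1,0.21
"S01","Hemiptera","order","invertebrate",1,0.21
"S02","Hemiptera","order","invertebrate",1,0.21
"S03","Hemiptera","order","invertebrate",1,0.21
"S04","Hemiptera","order","invertebrate",1,0.21
"S05","Hemiptera","order","invertebrate",1,0.21
"S06","Hemiptera","order","invertebrate",1,0.21
"S07","Hemiptera","order","invertebrate",1,0.21
"S08","Hemiptera","order","invertebrate",1,0.21
"S09","Hemiptera","order","invertebrate",1,0.21
"S10","Araneae","order","invertebrate",1,0.1625
"S01","Araneae","order","invertebrate",1,0.1625
"S02","Araneae","order","invertebrate",1,0.1625
"S03","Araneae","order","invertebrate",1,0.1625
"S04","Araneae","order","invertebrate",1,0.1625
"S05","Araneae","order","invertebrate",1,0.1625
"S06","Araneae","order","invertebrate",1,0.1625
"S07","Araneae","order","invertebrate",1,0.1625
"S08","Blattodea","order","invertebrate",1,0.5
"S09","Hymenoptera","order","invertebrate",1,0.1
"S10","Hymenoptera","order","invertebrate",1,0.1
"S01","Diptera","order","invertebrate",1,0.9
"S02","Odonata","order","invertebrate",1,0.3
"S03","Scorpiones","order","invertebrate",1,0.1
"S04","Scorpiones","order","invertebrate",1,0.1
"S11","Coleoptera","order","invertebrate",1,0.9
"S12","Coleoptera","order","invertebrate",1,0.9
"S13","Coleoptera","order","invertebrate",1,0.9
"S14","Coleoptera","order","invertebrate",1,0.9
"S15","Coleoptera","order","invertebrate",1,0.9
"S16","Coleoptera","order","invertebrate",1,0.9
"S17","Hemiptera","order","invertebrate",1,0.575
"S11","Hemiptera","order","invertebrate",1,0.575
"S12","Hemiptera","order","invertebrate",1,0.575
"S13","Hemiptera","order","invertebrate",1,0.575
"S14","Araneae","order","invertebrate",1,0.35
"S15","Araneae","order","invertebrate",1,0.35
"S16","Araneae","order","invertebrate",1,0.35
"S17","Araneae","order","invertebrate",1,0.35
"S11","Araneae","order","invertebrate",1,0.35
"S12","Araneae","order","invertebrate",1,0.35
"S13","Blattodea","order","invertebrate",1,1.3
"S14","Hymenoptera","order","invertebrate",1,0.433333333333333
"S15","Hymenoptera","order","invertebrate",1,0.433333333333333
"S16","Hymenoptera","order","invertebrate",1,0.433333333333333
"S17","Fish","class","vertebrate",1,0.3
"S11","Diptera","order","invertebrate",1,0.1
"S12","Odonata","order","invertebrate",1,0.5
"S13","Scorpiones","order","invertebrate",1,0.2
"S18","Coleoptera","order","invertebrate",1,0.408333333333333
"S19","Coleoptera","order","invertebrate",1,0.408333333333333
"S20","Coleoptera","order","invertebrate",1,0.408333333333333
"S21","Coleoptera","order","invertebrate",1,0.408333333333333
"S22","Coleoptera","order","invertebrate",1,0.408333333333333
"S23","Coleoptera","order","invertebrate",1,0.408333333333333
"S24","Coleoptera","order","invertebrate",1,0.408333333333333
"S25","Coleoptera","order","invertebrate",1,0.408333333333333
"S26","Coleoptera","order","invertebrate",1,0.408333333333333
"S27","Coleoptera","order","invertebrate",1,0.408333333333333
"S28","Coleoptera","order","invertebrate",1,0.408333333333333
"S29","Coleoptera","order","invertebrate",1,0.408333333333333
"S30","Hemiptera","order","invertebrate",1,0.311111111111111
"S31","Hemiptera","order","invertebrate",1,0.311111111111111
"S18","Hemiptera","order","invertebrate",1,0.311111111111111
"S19","Hemiptera","order","invertebrate",1,0.311111111111111
"S20","Hemiptera","order","invertebrate",1,0.311111111111111
"S21","Hemiptera","order","invertebrate",1,0.311111111111111
"S22","Hemiptera","order","invertebrate",1,0.311111111111111
"S23","Hemiptera","order","invertebrate",1,0.311111111111111
"S24","Hemiptera","order","invertebrate",1,0.311111111111111
"S25","Araneae","order","invertebrate",1,0.411111111111111
"S26","Araneae","order","invertebrate",1,0.411111111111111
"S27","Araneae","order","invertebrate",1,0.411111111111111
"S28","Araneae","order","invertebrate",1,0.411111111111111
"S29","Araneae","order","invertebrate",1,0.411111111111111
"S30","Araneae","order","invertebrate",1,0.411111111111111
"S31","Araneae","order","invertebrate",1,0.411111111111111
"S18","Araneae","order","invertebrate",1,0.411111111111111
"S19","Araneae","order","invertebrate",1,0.411111111111111
"S20","Blattodea","order","invertebrate",1,0.525
"S21","Blattodea","order","invertebrate",1,0.525
"S22","Blattodea","order","invertebrate",1,0.525
"S23","Blattodea","order","invertebrate",1,0.525
"S24","Hymenoptera","order","invertebrate",1,0.233333333333333
"S25","Hymenoptera","order","invertebrate",1,0.233333333333333
"S26","Hymenoptera","order","invertebrate",1,0.233333333333333
"S27","Hymenoptera","order","invertebrate",1,0.233333333333333
"S28","Hymenoptera","order","invertebrate",1,0.233333333333333
"S29","Hymenoptera","order","invertebrate",1,0.233333333333333
"S30","Fish","class","vertebrate",1,0.5
"S31","Fish","class","vertebrate",1,0.5
"S18","Fish","class","vertebrate",1,0.5
"S19","Fish","class","vertebrate",1,0.5
"S20","Birds","class","vertebrate",1,1.3
"S21","Diptera","order","invertebrate",1,0.15
"S22","Diptera","order","invertebrate",1,0.15
"S23","Odonata","order","invertebrate",1,0.1
"S24","Scorpiones","order","invertebrate",1,0.15
"S25","Scorpiones","order","invertebrate",1,0.15
"S26","Gastropods","class","invertebrate",1,0.05
"S27","Gastropods","class","invertebrate",1,0.05
"S28","Gastropods","class","invertebrate",1,0.05
"S29","Gastropods","class","invertebrate",1,0.05
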