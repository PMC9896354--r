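subject_id,latent_openness,planted_score,fear,net_sentiment,pos_units,neg_units,anger,anticipation,disgust,joy,sadness,surprise,trust
S001,39.60248651,39,30,-6,13,0,6,11,5,11,12,3,16
S002,30.79374005,30,24,-2,10,0,2,10,3,12,16,1,20
S003,32.58279412,33,25,15,11,0,0,9,1,7,14,2,19
S004,2.648311071,3,6,4,1,0,3,9,6,15,8,3,18
S005,45.54588645,45,28,4,15,0,4,7,5,10,6,2,23
S006,1.571433419,3,30,1,1,0,3,5,4,4,15,1,23
S007,16.00001237,15,11,8,5,0,3,9,6,16,13,2,9
S008,22.97526387,24,13,-2,8,0,2,8,5,8,9,1,17
S009,31.02739395,30,7,0,10,0,6,7,2,12,9,1,23
S010,42.95848295,42,16,20,14,0,3,8,5,7,15,1,11
S011,28.97421434,30,19,19,10,0,2,7,4,8,13,1,16
S012,14.98774034,15,14,11,5,0,4,10,3,7,9,1,18
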