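subject_id,age,sex,education,marital_status,employed,cancer_status,test_result,informational_support,communication_preference,perceived_utility,iri_total
S001,45,female,elementary_high_school,married,0,unaffected,positive,6,2,7,125
S002,64,male,university_postgraduate,married,1,affected,positive,5,3,5,193
S003,56,female,university_postgraduate,divorced_separated_widowed,0,affected,positive,5,3,6,214
S004,55,female,technical_school_graduate,married,0,affected,positive,4,1,6,145
S005,53,female,technical_school_graduate,married,1,unaffected,positive,6,1,6,196
S006,63,female,university_postgraduate,married,1,unaffected,positive,4,4,6,131
S007,44,female,university_postgraduate,married,1,affected,positive,5,2,5,144
S008,52,female,high_school_graduate,married,0,affected,positive,5,4,6,108
S009,70,male,university_postgraduate,married,1,affected,positive,5,4,5,187
S010,30,female,high_school_graduate,married,1,affected,positive,6,1,6,175
S011,67,female,university_postgraduate,single,1,unaffected,positive,3,3,6,150
S012,59,female,high_school_graduate,divorced_separated_widowed,0,affected,positive,5,3,6,161
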