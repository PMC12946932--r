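item,term,frequency_weight
S1,loss of interest,1
S1,little interest,1
S1,no pleasure,1
S1,lost interest,1
S1,nothing excites me,1
S1,stopped enjoying,1
S2,feeling down,1
S2,depressed,1
S2,hopeless,1
S2,feeling sad,1
S2,low mood,1
S2,crying a lot,1
S3,trouble sleeping,1
S3,cannot sleep,1
S3,insomnia,1
S3,sleeping too much,1
S3,waking up at night,1
S3,trouble falling asleep,1
S4,feeling tired,1
S4,no energy,1
S4,fatigue,1
S4,exhausted,1
S4,worn out,1
S4,drained,1
S5,poor appetite,1
S5,overeating,1
S5,no appetite,1
S5,eating too much,1
S5,skipping meals,1
S5,binge eating,1
S6,feeling like a failure,1
S6,worthless,1
S6,let my family down,1
S6,bad about myself,1
S6,guilty,1
S6,hate myself,1
S7,trouble concentrating,1
S7,cannot focus,1
S7,hard to concentrate,1
S7,mind wanders,1
S7,difficulty concentrating,1
S7,cannot pay attention,1
S8,moving slowly,1
S8,restless,1
S8,fidgety,1
S8,slowed down,1
S8,cannot sit still,1
S8,talking slowly,1
S9,better off dead,1
S9,hurting myself,1
S9,suicidal thoughts,1
S9,thoughts of death,1
S9,end my life,1
S9,self harm,1
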