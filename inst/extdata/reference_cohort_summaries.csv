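# Reported group summary statistics from the original study cohort
# (19 svPPA, 26 lvPPA, 25 nfvPPA, 31 healthy controls; picnic-scene task).
# raw_cu: de-duplicated content-unit count per participant.
# informativeness_pct: 100 * raw CUs / total utterances.
# utterances: total verbalization attempts (words, fillers, false starts);
#   method is blank because utterance counts do not depend on the CU scheme.
method,group,measure,n,mean,sd
original,HC,raw_cu,31,28.5,6.46
original,lvPPA,raw_cu,26,14.5,5.81
original,nfvPPA,raw_cu,25,20.3,6.07
original,svPPA,raw_cu,19,13.0,5.67
original,HC,informativeness_pct,31,20.9,5.67
original,lvPPA,informativeness_pct,26,11.7,5.18
original,nfvPPA,informativeness_pct,25,23.1,9.45
original,svPPA,informativeness_pct,19,11.1,6.46
uniqueref,HC,raw_cu,31,30.0,7.99
uniqueref,lvPPA,raw_cu,26,14.8,6.07
uniqueref,nfvPPA,raw_cu,25,20.8,6.19
uniqueref,svPPA,raw_cu,19,13.7,6.24
uniqueref,HC,informativeness_pct,31,21.9,5.87
uniqueref,lvPPA,informativeness_pct,26,11.9,5.26
uniqueref,nfvPPA,informativeness_pct,25,23.5,9.31
uniqueref,svPPA,informativeness_pct,19,11.7,7.02
,HC,utterances,31,150,65.9
,svPPA,utterances,19,135,53.6
,lvPPA,utterances,26,135,60.3
,nfvPPA,utterances,25,97.1,34.1
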