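day_type,direction,hour,minutes
weekday,urban_to_suburban,0,52
weekday,urban_to_suburban,1,51
weekday,urban_to_suburban,2,50
weekday,urban_to_suburban,3,50
weekday,urban_to_suburban,4,51
weekday,urban_to_suburban,5,54
weekday,urban_to_suburban,6,60
weekday,urban_to_suburban,7,64
weekday,urban_to_suburban,8,66
weekday,urban_to_suburban,9,65
weekday,urban_to_suburban,10,64
weekday,urban_to_suburban,11,66
weekday,urban_to_suburban,12,74
weekday,urban_to_suburban,13,80
weekday,urban_to_suburban,14,86
weekday,urban_to_suburban,15,90
weekday,urban_to_suburban,16,93
weekday,urban_to_suburban,17,90
weekday,urban_to_suburban,18,84
weekday,urban_to_suburban,19,66
weekday,urban_to_suburban,20,62
weekday,urban_to_suburban,21,58
weekday,urban_to_suburban,22,55
weekday,urban_to_suburban,23,53
weekday,suburban_to_urban,0,52
weekday,suburban_to_urban,1,51
weekday,suburban_to_urban,2,50
weekday,suburban_to_urban,3,50
weekday,suburban_to_urban,4,52
weekday,suburban_to_urban,5,58
weekday,suburban_to_urban,6,86
weekday,suburban_to_urban,7,90
weekday,suburban_to_urban,8,88
weekday,suburban_to_urban,9,76
weekday,suburban_to_urban,10,68
weekday,suburban_to_urban,11,66
weekday,suburban_to_urban,12,66
weekday,suburban_to_urban,13,67
weekday,suburban_to_urban,14,72
weekday,suburban_to_urban,15,76
weekday,suburban_to_urban,16,78
weekday,suburban_to_urban,17,72
weekday,suburban_to_urban,18,64
weekday,suburban_to_urban,19,60
weekday,suburban_to_urban,20,57
weekday,suburban_to_urban,21,55
weekday,suburban_to_urban,22,54
weekday,suburban_to_urban,23,52
weekend,urban_to_suburban,0,52
weekend,urban_to_suburban,1,49
weekend,urban_to_suburban,2,48
weekend,urban_to_suburban,3,48
weekend,urban_to_suburban,4,49
weekend,urban_to_suburban,5,52
weekend,urban_to_suburban,6,54
weekend,urban_to_suburban,7,56
weekend,urban_to_suburban,8,57
weekend,urban_to_suburban,9,57
weekend,urban_to_suburban,10,60
weekend,urban_to_suburban,11,64
weekend,urban_to_suburban,12,65
weekend,urban_to_suburban,13,65
weekend,urban_to_suburban,14,65
weekend,urban_to_suburban,15,65
weekend,urban_to_suburban,16,64
weekend,urban_to_suburban,17,64
weekend,urban_to_suburban,18,62
weekend,urban_to_suburban,19,60
weekend,urban_to_suburban,20,56
weekend,urban_to_suburban,21,54
weekend,urban_to_suburban,22,52
weekend,urban_to_suburban,23,50
weekend,suburban_to_urban,0,56
weekend,suburban_to_urban,1,55
weekend,suburban_to_urban,2,54
weekend,suburban_to_urban,3,53
weekend,suburban_to_urban,4,54
weekend,suburban_to_urban,5,55
weekend,suburban_to_urban,6,56
weekend,suburban_to_urban,7,56
weekend,suburban_to_urban,8,57
weekend,suburban_to_urban,9,57
weekend,suburban_to_urban,10,57
weekend,suburban_to_urban,11,60
weekend,suburban_to_urban,12,60
weekend,suburban_to_urban,13,60
weekend,suburban_to_urban,14,60
weekend,suburban_to_urban,15,60
weekend,suburban_to_urban,16,60
weekend,suburban_to_urban,17,60
weekend,suburban_to_urban,18,60
weekend,suburban_to_urban,19,57
weekend,suburban_to_urban,20,56
weekend,suburban_to_urban,21,56
weekend,suburban_to_urban,22,55
weekend,suburban_to_urban,23,54
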