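step	metric	root	leaf	flower	seed	total
input	unique	6755739	6901052	8538019	5798159	22829317
input	total	23852494	24059282	23741532	25494472	97147780
adapter_polyN_removed	unique	5787223	5802483	7347504	4856499	19207362
adapter_polyN_removed	total	20618934	20514477	20496815	22312078	83942304
low_count_filtered	unique	1193873	1161516	1231736	1079437	1697668
low_count_filtered	total	15463951	15293812	13668993	18097032	62523788
contaminant_removed	unique	1164475	1117720	1206840	1047951	1649996
contaminant_removed	total	15117306	13507134	13408510	17354424	59387374
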