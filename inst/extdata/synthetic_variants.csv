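"variant_id","p119","p124","p130","p133","p235","p302","p308","p309","p310","p320","p395","p474","p476"
"WT","K","C","K","I","F","E","P","D","T","F","I","I","D"
"V01","V","C","V","I","F","E","P","D","T","F","I","I","D"
"V02","K","C","K","I","C","W","P","D","T","F","I","I","D"
"V03","K","C","K","I","F","E","C","D","T","F","I","I","W"
"V04","K","C","K","I","F","E","P","D","H","H","I","I","D"
"V05","K","C","K","V","F","E","P","D","T","F","G","I","D"
"V06","K","T","K","I","F","E","P","D","T","F","I","G","D"
"V07","K","C","K","I","F","E","P","N","T","F","I","I","D"
"V08","S","C","K","I","F","E","P","D","T","F","I","I","D"
"V09","K","C","K","I","K","E","P","D","T","F","I","I","D"
"V10","K","C","K","I","F","E","P","D","T","P","I","I","E"
"V11","K","C","K","I","F","E","P","D","E","F","L","I","D"
"V12","K","D","K","W","F","E","P","D","T","F","I","I","D"
"V13","K","V","K","I","F","E","P","D","T","F","I","I","D"
"V14","K","C","K","I","F","E","P","M","T","F","I","I","D"
"V15","H","C","C","I","F","E","P","D","T","F","I","I","D"
"V16","K","C","K","I","D","E","P","D","T","F","I","I","D"
"V17","K","C","K","I","F","E","P","D","T","F","M","I","V"
"V18","K","C","K","I","F","E","P","D","P","F","I","I","D"
"V19","K","C","K","F","F","E","P","D","T","F","I","I","D"
"V20","K","P","K","I","F","M","P","D","T","F","I","I","D"
"V21","K","C","K","I","F","E","P","W","T","F","I","I","D"
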