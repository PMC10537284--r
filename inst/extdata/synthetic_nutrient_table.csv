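food,protein,fat,fiber,carbohydrate,minerals,water
rice,7.280,1.100,0.332,25.516,0.268,45.846
stewed_pork,8.466,6.986,4.239,32.207,0.727,36.503
fried_chicken,4.548,20.820,1.713,30.351,0.335,37.435
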