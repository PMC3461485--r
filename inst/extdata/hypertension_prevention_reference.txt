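Maintain normal body weight
Reduce sodium intake
Increased daily life activity
Higher folate intake
Regular aerobic physical activity
Diet reduced in saturated and total fat
Walking to work
Increased plant food intake
Diet rich in fruits, vegetables and low- fat dairy products
Relaxation
Whole-grain intake
Regular tea consumption
Limit alcohol use
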