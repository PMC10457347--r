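name,formula,adduct,printed_mz,expected_ook0,verified
PC (32:1),C40H78NO8P,[M+H]+,732.5537,,TRUE
PC (32:0),C40H80NO8P,[M+H]+,734.5676,,TRUE
PC (34:2),C42H80NO8P,[M+H]+,758.5685,,TRUE
PC (34:1),C42H82NO8P,[M+H]+,760.5854,,TRUE
PC (O-36:2),C44H86NO7P,[M+H]+,772.5846,,FALSE
PC (36:4),C44H80NO8P,[M+H]+,782.5685,,TRUE
PC (36:2),C44H84NO8P,[M+H]+,786.5933,,TRUE
PC (18:1-18:1),C44H84NO8P,[M+H]+,786.6007,,TRUE
PC (36:1),C44H86NO8P,[M+H]+,788.6135,,TRUE
PC (38:4),C46H84NO8P,[M+H]+,810.6052,,TRUE
PC (38:3),C46H86NO8P,[M+H]+,812.6139,,TRUE
PC (O-36:4),C44H82NO7P,[M+H]+,768.5853,,TRUE
PC (O-32:0),C40H82NO7P,[M+H]+,720.5866,1.4416,TRUE
PE (34:0),C39H78NO8P,[M+H]+,720.5497,1.4178,TRUE
PE (36:0),C41H82NO8P,[M+H]+,748.5827,,TRUE
LPC (18:1),C26H52NO7P,[M+H]+,522.3545,,TRUE
Cer (34:1;O2),C34H67NO3,[M+H-H2O]+,520.5044,,TRUE
Cer (40:1;O2),C40H79NO3,[M+H-H2O]+,604.6003,,TRUE
Cer (42:3;O),C42H79NO2,[M+H]+,630.6186,,TRUE
PE (36:1),C41H80NO8P,[M-H]-,744.5552,,TRUE
PS (36:1),C42H80NO10P,[M-H]-,788.5429,,TRUE
PI (38:4),C47H83O13P,[M-H]-,885.5477,,TRUE
FA (16:0),C16H32O2,[M-H]-,255.2167,,FALSE
FA (16:1),C16H30O2,[M-H]-,253.2143,,FALSE
FA (18:1),C18H34O2,[M-H]-,281.2476,,TRUE
FA (18:0),C18H36O2,[M-H]-,283.2657,,TRUE
FA (20:3),C20H34O2,[M-H]-,305.2434,,FALSE
FA (20:1),C20H38O2,[M-H]-,309.2795,,TRUE
FA (22:1),C22H42O2,[M-H]-,337.3074,,FALSE
LPE (18:1),C23H46NO7P,[M-H]-,478.2967,,TRUE
LPE (20:1),C25H50NO7P,[M-H]-,506.3261,,TRUE
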