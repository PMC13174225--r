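{"qtl_temperature_sensitive":{"intercept":1.89561478388701,"beta_g":0.0544284244189166,"beta_e":1.06323008805222,"beta_d":0.0323365035777256,"beta_gxe":-0.000195057124747065,"beta_dxe":-0.00108460001600501,"partners":{"p15":{"af":0.03,"beta_p":0.0571757021226684,"beta_pxe":0.0137131740572409,"beta_gxg":0.0316614885090994,"beta_gxgxe":-0.0039087941102572},"p21":{"af":0.005,"beta_p":0.0349932742176594,"beta_pxe":0.0130941885895847,"beta_gxg":0.00952812387929101,"beta_gxgxe":-0.0038189992559083}},"sigma2":0.00460358879964288},"qtl_additive":{"intercept":1.9589478955425,"beta_g":0.0531181247656881,"beta_e":1.04862418375358,"beta_d":0.00526116292640913,"beta_gxe":-0.000656587309503694,"beta_dxe":-0.000801790333076605,"partners":{"p15":{"af":0.03,"beta_p":0.0595921505435875,"beta_pxe":0.0076090798359086,"beta_gxg":0,"beta_gxgxe":0},"p21":{"af":0.005,"beta_p":0.0466211199766753,"beta_pxe":0.00614821875778622,"beta_gxg":0,"beta_gxgxe":0}},"sigma2":0.00486248325518398},"qtl_overdominant":{"intercept":1.92773202842881,"beta_g":0.0219572165436835,"beta_e":1.05813560674328,"beta_d":0.00279198792227552,"beta_gxe":-0.00371800756655216,"beta_dxe":0.0125481883825668,"partners":{"p15":{"af":0.03,"beta_p":0.0751290804649537,"beta_pxe":0.00275595380275599,"beta_gxg":0,"beta_gxgxe":0},"p21":{"af":0.005,"beta_p":0.0406592641338194,"beta_pxe":0.00985509188262835,"beta_gxg":0,"beta_gxgxe":0}},"sigma2":0.00478103457805622}}
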