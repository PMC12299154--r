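# Packaged default parameters: abortion hazards and type split (De Vries 2006;
# Keshavarzi et al. 2017), abortion-type effects, and the economic scenario.
# carcass_weight and ai_cost are not part of the published tables; see the
# methods vignette for how the shipped defaults were fixed.
abortion:
  hazard:
    "2": 0.035
    "3": 0.025
    "4": 0.015
    "5": 0.005
    "6": 0.0025
    "7": 0.001
    "8": 0.001
  nla_odds_numerator: 1.9
  nla_odds_denominator: 12.5
effects:
  milk_reduction_ra: 0.073
  milk_reduction_nla: 0.194
  cull_risk_multiplier: 1.9
economics:
  milk_price: 0.36
  calf_value: 100
  carcass_price: 1.16
  replacement_cost: 1300
  vet_cost: 50
  feed_cost_lact: 0.17
  feed_cost_dry: 0.13
  dmi: 25
  days_per_month: 30
  ai_cost: 35
  carcass_weight: 563
  twin_loss: 0
  dry_off_preg: 10
  max_milking_mil: 12
policy:
  cull_mil_primiparous: 11
  cull_mil_multiparous: 10
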