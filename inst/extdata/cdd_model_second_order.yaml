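name: cdd_second_order
observed:
- motor
- vision
- feeding
- communication_clin
- csbs
- insomnia
- sleepiness
- seizures
- alertness
latents:
- communication
- comorbidities
- global
measurement:
  communication:
    communication_clin: 1.0
    csbs: free
  comorbidities:
    insomnia: 1.0
    sleepiness: free
    seizures: free
    alertness: free
  global:
    motor: 1.0
    vision: free
    feeding: free
structural:
- from: global
  to: communication
- from: global
  to: comorbidities
covariances: []
latent_variances:
  communication: free
  comorbidities: free
  global: free
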