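populations:
  pyr: 800
  pv: 200
  olm: 200
reversals:
  ampa: 0.0
  nmda: 0.0
  gaba_a: -80.0
  leak: -65.0
  ih: -30.0
  na: 55.0
  k: -90.0
  ca: 120.0
mg_mM: 1.0
cells:
  pyr:
    compartments:
      name:
      - Bdend
      - soma
      - Adend1
      - Adend2
      - Adend3
      parent:
      - soma
      - .na.character
      - soma
      - Adend1
      - Adend2
      L_um:
      - 200.0
      - 20.0
      - 150.0
      - 150.0
      - 150.0
      diam_um:
      - 2.0
      - 20.0
      - 2.0
      - 2.0
      - 2.0
    channels:
      leak:
        Bdend: 0.1
        soma: 0.1
        Adend1: 0.1
        Adend2: 0.1
        Adend3: 0.1
      NaF:
        Bdend: 25.0
        soma: 100.0
        Adend1: 25.0
        Adend2: 25.0
        Adend3: 25.0
      KDR:
        Bdend: 10.0
        soma: 80.0
        Adend1: 10.0
        Adend2: 10.0
        Adend3: 10.0
      KA:
        Bdend: 10.0
        soma: 30.0
        Adend1: 15.0
        Adend2: 20.0
        Adend3: 25.0
      Ih:
        Bdend: 0.0075
        soma: 0.0075
        Adend1: 0.015
        Adend2: 0.03
        Adend3: 0.06
    e_leak: -65.0
  pv:
    compartments:
      name: soma
      parent: .na
      L_um: 20.0
      diam_um: 20.0
    channels:
      leak:
        soma: 0.4
      NaF:
        soma: 150.0
      KDR:
        soma: 100.0
      Ih:
        soma: 0.025
    e_leak: -65.0
  olm:
    compartments:
      name: soma
      parent: .na
      L_um: 20.0
      diam_um: 20.0
    channels:
      leak:
        soma: 0.05
      NaF:
        soma: 100.0
      KDR:
        soma: 70.0
      Ih:
        soma: 0.15
      CaL:
        soma: 0.5
      KCa:
        soma: 5.0
    e_leak: -65.0
    ca_alpha: 0.002
cm_uF_cm2: 1.0
ra_ohm_cm: 150.0
synapses:
  pre:
  - pyr
  - pyr
  - pyr
  - pyr
  - pyr
  - pyr
  - pv
  - pv
  - pv
  - olm
  post:
  - pyr
  - pyr
  - pv
  - pv
  - olm
  - olm
  - pyr
  - pv
  - olm
  - pyr
  receptor:
  - AMPA
  - NMDA
  - AMPA
  - NMDA
  - AMPA
  - NMDA
  - GABA_A
  - GABA_A
  - GABA_A
  - GABA_A
  tau1:
  - 0.05
  - 15.0
  - 0.05
  - 15.0
  - 0.05
  - 15.0
  - 0.07
  - 0.07
  - 0.07
  - 0.2
  tau2:
  - 5.3
  - 150.0
  - 5.3
  - 150.0
  - 5.3
  - 150.0
  - 9.1
  - 9.1
  - 9.1
  - 20.0
  gmax_nS:
  - 0.02
  - 0.004
  - 0.36
  - 1.38
  - 0.36
  - 0.7
  - 0.72
  - 4.5
  - 0.023
  - 72.0
  convergence:
  - 25
  - 25
  - 100
  - 100
  - 10
  - 10
  - 50
  - 60
  - 1
  - 20
  target:
  - Adend2
  - Adend2
  - soma
  - soma
  - soma
  - soma
  - soma
  - soma
  - soma
  - Adend3
background:
  pop:
  - pyr
  - pyr
  - pyr
  - pyr
  - pyr
  - pv
  - pv
  - olm
  - olm
  target:
  - soma
  - soma
  - Adend3
  - Adend3
  - Adend3
  - soma
  - soma
  - soma
  - soma
  receptor:
  - AMPA
  - GABA_A
  - AMPA
  - NMDA
  - GABA_A
  - AMPA
  - GABA_A
  - AMPA
  - GABA_A
  tau1:
  - 0.05
  - 0.07
  - 0.05
  - 15.0
  - 0.07
  - 0.05
  - 0.07
  - 0.05
  - 0.07
  tau2:
  - 5.3
  - 9.1
  - 5.3
  - 150.0
  - 9.1
  - 5.3
  - 9.1
  - 5.3
  - 9.1
  gmax_nS:
  - 0.05
  - 0.012
  - 0.05
  - 6.5
  - 0.012
  - 0.02
  - 0.2
  - 0.0625
  - 0.2
  rate_hz:
  - 150.0
  - 150.0
  - 150.0
  - 45.0
  - 150.0
  - 100.0
  - 150.0
  - 200.0
  - 150.0
ms_drive:
  freq_hz: 6.7
  jitter_ms: 6.0
  events_per_volley: 5.0
  period_sd_ms: 14.0
  targets:
  - pv
  - olm
  receptor: GABA_A
  tau1: 0.07
  tau2: 9.1
  gmax_nS:
    pv: 10.0
    olm: 10.0
simulation:
  duration_ms: 7000.0
  analysis_start_ms: 2000.0
  dt_ms: 0.1
  record_interval_ms: 1.0
  spike_threshold_mV: 0.0
  lockout_ms: 1.0
  synaptic_delay_ms: 6.0
  v_init_mV: -65.0
  v_init_jitter_mV: 2.0
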