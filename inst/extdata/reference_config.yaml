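# Reference configuration of the studied laboratory batch bioreactor:
# identified kinetic and temperature-coupling parameters, measured
# initial loading (declared in mg/L, converted to g/L on load), and the
# canonical step protocol used for coupling identification.
parameters:
  mu_m: 2.1        # 1/h
  P_i: 0.75        # g/L
  S_m: 0.03        # g/L
  S_i: 1.0         # g/L
  alpha: 0.38      # g/L per g/L
  beta: 0.002      # 1/h
coupling:
  k_mu: 0.14       # 1/degC
  k_alpha: 0.03    # 1/degC
  T_theta_cs: 0.1  # h
  theta_0: 22      # degC
initial_state:
  unit: "mg/L"
  x1: 2.6
  x2: 9.0
  x3: 0.1
  temp_C: 22
protocol:
  type: step
  theta_start: 22
  theta_end: 27
  t_step: 3        # h
simulation:
  t_end: 24        # h
  dt_sample: 0.16666666666666666  # 10 min
seed: 1
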