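{
  "version": 1,
  "description": "Versioned biophysical and network constants for the modified Mainen model neuron and the feedforward network. Conductance densities in pS/um^2, potentials in mV, capacitance in uF/cm^2, times in ms, currents in pA. Rate amplitudes in s^-1 mV^-1 (linoid forms) or s^-1 (saturating forms); the code converts to ms^-1.",
  "membrane": {
    "c_m": 1.0,
    "e_na": 60.0,
    "e_k": -90.0,
    "e_leak": -70.0,
    "g_leak": 0.056,
    "patch_radius": 30.0,
    "area_convention": "disc",
    "spike_threshold": -20.0,
    "refractory": 2.0,
    "dt": 0.025
  },
  "conductances": {
    "GS":  { "g_na": 1500.0, "g_k": 1000.0 },
    "NGS": { "g_na": 600.0,  "g_k": 1000.0 }
  },
  "kinetics": {
    "m": {
      "alpha": { "amplitude": 182.0, "v_half": -35.0, "k": 9.0, "form": "linoid_up" },
      "beta":  { "amplitude": 124.0, "v_half": -35.0, "k": 9.0, "form": "linoid_down" }
    },
    "h": {
      "alpha": { "amplitude": 24.0, "v_half": -50.0, "k": 5.0, "form": "linoid_up" },
      "beta":  { "amplitude": 9.1,  "v_half": -75.0, "k": 5.0, "form": "linoid_down" },
      "steady_state": { "v_half": -65.0, "k": 6.2 }
    },
    "n": {
      "alpha": { "amplitude": 20.0, "v_half": 20.0, "k": 9.0, "form": "linoid_up" },
      "beta":  { "amplitude": 2.0,  "v_half": 20.0, "k": 9.0, "form": "linoid_down" }
    }
  },
  "stimulus": {
    "tau_ou": 1.0,
    "slow_cutoff_hz": 1.0,
    "ramp_rise_ms": 50.0,
    "lowpass_tau_ms": 500.0
  },
  "synapse": {
    "tau_syn": 5.0,
    "e_ex": 0.0,
    "w_weak": 0.04,
    "w_strong": 0.06
  },
  "network": {
    "n_layers": 10,
    "n_per_layer": 2000,
    "p_connect": 0.05,
    "noise_sigma": 15.0
  },
  "fi_grid": {
    "dc_min": 0.0, "dc_max": 120.0, "dc_step": 2.5,
    "sigma_min": 5.0, "sigma_max": 150.0, "sigma_step": 2.5,
    "duration_s": 100.0, "burn_in_s": 1.0
  }
}
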