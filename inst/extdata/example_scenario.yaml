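# Reduced-scale demonstration scenario: 50-hr phenotypic persistence,
# responder bias 0.5, all switched cells responders.
domain_um: 1500
init_radius_um: 250
Tp: 3000        # minutes (50 hr); use .inf for permanent persistence
b_star: 0.5
Fr: 1.0
end_time_hr: 80
snapshot_interval_hr: 40
heterogeneous_sources: 0
pressure_feedback: false
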