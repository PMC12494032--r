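# Reference scenario: Treg pool assembly in seven mouse tissues.
#
# target_cumulative gives, per tissue, the corrected cumulative tagged
# fraction expected for pulses at weeks 1..6 analyzed at 8 weeks of age;
# the per-day influx is solved from this curve at load time. division is a
# piecewise-linear per-cell per-day division probability profile (knots in
# days of age). Loss rates are per day during the growth phase; after the
# analysis day each tissue switches to a constant-pool replacement regime
# with the stated per-week rates (resident cohorts / later influx).
name: paper_scenario
seed: 20260930
analysis_week: 8
horizon_days: 211
pulse_weeks: [1, 2, 3, 4, 5, 6]
mice_per_group: 8
kernel: [1, 1, 1, 1, 1, 0.66666667, 0.33333333, 0]
turnover:
  pulse_day: 70
  analysis_weeks: [11, 16, 20, 28]
tissues:
  spleen:
    efficiency: 0.96
    target_cumulative: [0.12, 0.35, 0.50, 0.62, 0.70, 0.76]
    division: {days: [0, 14, 49, 210], probs: [0.30, 0.30, 0.055, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.02
    residency_cutoff_day: 7
    adult_loss_resident_per_week: 0.0
    adult_replacement_per_week: 0.055
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.15, untag: 0.04}
      ST2: {tag: 0.12, untag: 0.03}
      CCR2: {tag: 0.18, untag: 0.05}
  LN:
    efficiency: 0.96
    target_cumulative: [0.10, 0.25, 0.38, 0.50, 0.60, 0.68]
    division: {days: [0, 14, 49, 210], probs: [0.30, 0.30, 0.055, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.02
    residency_cutoff_day: 7
    adult_loss_resident_per_week: 0.0
    adult_replacement_per_week: 0.055
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.12, untag: 0.04}
      ST2: {tag: 0.10, untag: 0.03}
      CCR2: {tag: 0.15, untag: 0.05}
  lungs:
    efficiency: 0.95
    target_cumulative: [0.15, 0.50, 0.62, 0.70, 0.78, 0.84]
    division: {days: [0, 14, 49, 210], probs: [0.33, 0.33, 0.055, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.015
    residency_cutoff_day: 14
    adult_loss_resident_per_week: 0.0
    adult_replacement_per_week: 0.05
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.40, untag: 0.15}
      ST2: {tag: 0.35, untag: 0.12}
      CCR2: {tag: 0.35, untag: 0.15}
  liver:
    efficiency: 0.96
    target_cumulative: [0.15, 0.45, 0.60, 0.70, 0.78, 0.83]
    division: {days: [0, 14, 49, 210], probs: [0.33, 0.33, 0.055, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.015
    residency_cutoff_day: 14
    adult_loss_resident_per_week: 0.0
    adult_replacement_per_week: 0.05
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.45, untag: 0.15}
      ST2: {tag: 0.40, untag: 0.12}
      CCR2: {tag: 0.35, untag: 0.15}
  colon:
    efficiency: 0.95
    target_cumulative: [0.15, 0.40, 0.57, 0.68, 0.76, 0.82]
    division: {days: [0, 14, 49, 210], probs: [0.33, 0.33, 0.055, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.015
    residency_cutoff_day: 14
    adult_loss_resident_per_week: 0.0
    adult_replacement_per_week: 0.03
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.60, untag: 0.15}
      ST2: {tag: 0.45, untag: 0.15}
      CCR2: {tag: 0.50, untag: 0.20}
    subsets:
      GATA3:
        weight: 0.30
        target_cumulative: [0.35, 0.63, 0.72, 0.78, 0.82, 0.85]
        loss_resident: 0.001
        loss_flux: 0.012
        adult_loss_resident_per_week: 0.01
        adult_replacement_per_week: 0.02
      RORgt:
        weight: 0.50
        target_cumulative: [0.04, 0.12, 0.28, 0.48, 0.62, 0.72]
        loss_resident: 0.002
        loss_flux: 0.02
        residency_cutoff_day: 0
        adult_loss_resident_per_week: 0.0
        adult_replacement_per_week: 0.06
      DN:
        weight: 0.20
        target_cumulative: [0.30, 0.60, 0.67, 0.74, 0.78, 0.81]
        loss_resident: 0.001
        loss_flux: 0.012
        adult_loss_resident_per_week: 0.01
        adult_replacement_per_week: 0.02
  VAT:
    efficiency: 0.95
    target_cumulative: [0.37, 0.75, 0.84, 0.87, 0.89, 0.91]
    division: {days: [0, 14, 28, 56, 210], probs: [0.33, 0.33, 0.08, 0.02, 0.02]}
    loss_resident: 0.002
    loss_flux: 0.01
    residency_cutoff_day: 21
    adult_loss_resident_per_week: 0.065
    adult_replacement_per_week: 0.01
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.70, untag: 0.20}
      ST2: {tag: 0.75, untag: 0.25}
      CCR2: {tag: 0.60, untag: 0.20}
  skin:
    efficiency: 0.99
    target_cumulative: [0.60, 0.85, 0.88, 0.90, 0.91, 0.92]
    division: {days: [0, 13, 17, 56, 210], probs: [0.40, 0.40, 0.055, 0.02, 0.02]}
    loss_resident: 0.001
    loss_flux: 0.012
    residency_cutoff_day: 21
    adult_loss_resident_per_week: 0.027
    adult_replacement_per_week: 0.027
    sampled_cells: 2000
    kappa: 50
    markers:
      KLRG1: {tag: 0.65, untag: 0.25}
      ST2: {tag: 0.60, untag: 0.50}
      CCR2: {tag: 0.55, untag: 0.25}
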