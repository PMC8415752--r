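# Default ten-seed registry: four 4-mm spheres anchoring large-scale
# networks (12-mm-smoothed maps), four hippocampal long-axis bands and two
# basal-forebrain compartments (6-mm-smoothed maps). Label ids refer to the
# user-supplied atlas lookup; these defaults match the packaged synthetic
# atlas.
- name: R EC
  kind: sphere
  center_mni: [25, -9, -28]
  radius_mm: 4
  smoothing_fwhm_mm: 12
- name: L PCC
  kind: sphere
  center_mni: [-2, -36, 35]
  radius_mm: 4
  smoothing_fwhm_mm: 12
- name: R FIC
  kind: sphere
  center_mni: [38, 26, -10]
  radius_mm: 4
  smoothing_fwhm_mm: 12
- name: R DLPFC
  kind: sphere
  center_mni: [44, 36, 20]
  radius_mm: 4
  smoothing_fwhm_mm: 12
- name: L anterior hippocampus
  kind: coordinate_band
  atlas_labels: [4101]
  y_range_mm: [-18, -2]
  smoothing_fwhm_mm: 6
- name: R anterior hippocampus
  kind: coordinate_band
  atlas_labels: [4201]
  y_range_mm: [-18, -2]
  smoothing_fwhm_mm: 6
- name: L posterior hippocampus
  kind: coordinate_band
  atlas_labels: [4101]
  y_range_mm: [-42, -24]
  smoothing_fwhm_mm: 6
- name: R posterior hippocampus
  kind: coordinate_band
  atlas_labels: [4201]
  y_range_mm: [-42, -24]
  smoothing_fwhm_mm: 6
- name: Ch4p
  kind: atlas_labels
  atlas_labels: [9001]
  smoothing_fwhm_mm: 6
- name: Ch1/2
  kind: atlas_labels
  atlas_labels: [9002]
  smoothing_fwhm_mm: 6
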