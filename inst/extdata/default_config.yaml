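scenario:
  start_year: 1765.0
  stop_year: 2020.0
  end_year: 3000.0
  evaluation_year: 2650.0
  baseline_year: 1770.0
  spinup_years: 10000.0
  spinup_check_interval: 500.0
  drift_tol_pmol_yr: 0.0005
  emission_growth_rate: 0.01
  emission_end_rate_gtco2: 40.0
  expected_cumulative_gtco2: 3709.3
climate:
  co2_preind_uatm: 278.0
  forcing_coeff_w_m2: 5.35
  feedback_w_m2_k: 1.0
  atm_heat_capacity_j_k_m2: 1.0e+08
  gtc_per_uatm: 2.124
  land_sink_fraction: 0.58
  earth_area_m2: 5.101e+14
  sat_plateau_tol_c: 0.25
  surface_restore_years: 0.5
  surface_warming_factor:
    surf_lowlat: 0.92
    surf_natl: 1.1
    surf_npac: 0.92
    surf_so: 1.38
ocean:
  rho_kg_m3: 1026.5
  cp_j_kg_k: 3990.0
  salinity_psu: 34.7
geometry:
  boxes:
  - box: surf_lowlat
    basin: Indo-Pacific
    latitude_band: 50S-50N
    depth_top: 0.0
    depth_bottom: 100.0
    volume: 2.45e+16
    is_surface: yes
    area: 2.45e+14
    t_preind: 18.0
  - box: surf_natl
    basin: Atlantic
    latitude_band: 15N-60N
    depth_top: 0.0
    depth_bottom: 100.0
    volume: 3.0e+15
    is_surface: yes
    area: 3.0e+13
    t_preind: 4.0
  - box: surf_npac
    basin: Indo-Pacific
    latitude_band: 15N-60N
    depth_top: 0.0
    depth_bottom: 100.0
    volume: 3.5e+15
    is_surface: yes
    area: 3.5e+13
    t_preind: 6.0
  - box: surf_so
    basin: Southern
    latitude_band: 90S-50S
    depth_top: 0.0
    depth_bottom: 100.0
    volume: 5.0e+15
    is_surface: yes
    area: 5.0e+13
    t_preind: 0.8
  - box: thermo_atl
    basin: Atlantic
    latitude_band: 50S-50N
    depth_top: 100.0
    depth_bottom: 1200.0
    volume: 7.5e+16
    is_surface: no
    area: .na
    t_preind: .na
  - box: thermo_ip
    basin: Indo-Pacific
    latitude_band: 50S-50N
    depth_top: 100.0
    depth_bottom: 1200.0
    volume: 2.1e+17
    is_surface: no
    area: .na
    t_preind: .na
  - box: thermo_so
    basin: Southern
    latitude_band: 90S-50S
    depth_top: 100.0
    depth_bottom: 1200.0
    volume: 6.0e+16
    is_surface: no
    area: .na
    t_preind: .na
  - box: mid_atl
    basin: Atlantic
    latitude_band: 50S-50N
    depth_top: 1200.0
    depth_bottom: 2000.0
    volume: 5.5e+16
    is_surface: no
    area: .na
    t_preind: .na
  - box: mid_ip
    basin: Indo-Pacific
    latitude_band: 50S-50N
    depth_top: 1200.0
    depth_bottom: 2000.0
    volume: 1.6e+17
    is_surface: no
    area: .na
    t_preind: .na
  - box: deep_atl
    basin: Atlantic
    latitude_band: 50S-50N
    depth_top: 2000.0
    depth_bottom: 4000.0
    volume: 1.4e+17
    is_surface: no
    area: .na
    t_preind: .na
  - box: deep_ip
    basin: Indo-Pacific
    latitude_band: 50S-50N
    depth_top: 2000.0
    depth_bottom: 4000.0
    volume: 4.0e+17
    is_surface: no
    area: .na
    t_preind: .na
  - box: bottom_so
    basin: Southern
    latitude_band: 90S-50S
    depth_top: 2000.0
    depth_bottom: 5000.0
    volume: 1.64e+17
    is_surface: no
    area: .na
    t_preind: .na
  cells:
  - name: amoc
    psi_sv: 16.0
    path:
    - surf_lowlat
    - surf_natl
    - deep_atl
    - mid_atl
    - thermo_atl
    - surf_lowlat
  - name: so_abyssal
    psi_sv: 13.0
    path:
    - surf_so
    - bottom_so
    - deep_ip
    - mid_ip
    - thermo_ip
    - thermo_so
    - surf_so
  mixing:
  - from: surf_lowlat
    to: thermo_atl
    sv: 9.0
  - from: surf_lowlat
    to: thermo_ip
    sv: 30.0
  - from: surf_npac
    to: thermo_ip
    sv: 5.0
  - from: surf_npac
    to: surf_lowlat
    sv: 1.0
  - from: surf_so
    to: thermo_so
    sv: 6.0
  - from: surf_so
    to: bottom_so
    sv: 0.5
  - from: thermo_so
    to: thermo_atl
    sv: 0.5
  - from: thermo_so
    to: thermo_ip
    sv: 4.0
  - from: thermo_so
    to: bottom_so
    sv: 1.0
  - from: thermo_atl
    to: mid_atl
    sv: 1.0
  - from: mid_atl
    to: deep_atl
    sv: 1.0
  - from: thermo_ip
    to: mid_ip
    sv: 2.0
  - from: mid_ip
    to: deep_ip
    sv: 2.0
  - from: deep_ip
    to: bottom_so
    sv: 1.5
  - from: deep_atl
    to: bottom_so
    sv: 1.0
  columns:
    surf_lowlat:
      thermo_atl: thermo
      thermo_ip: thermo
      mid_atl: mid
      mid_ip: mid
      deep_atl: deep
      deep_ip: deep
      bottom_so: bottom
    surf_natl:
      thermo_atl: thermo
      mid_atl: mid
      deep_atl: deep
    surf_npac:
      thermo_ip: thermo
      mid_ip: mid
      deep_ip: deep
    surf_so:
      thermo_so: thermo
      bottom_so: bottom
  lowlat_atl_share: 0.26
transport:
  alpha_so_per_k: 0.46
  amoc_dip_per_k: 0.5
  amoc_recovery_gain: 0.18
  amoc_integral_scale_k_yr: 200.0
  psi_floor_frac: 0.2
  surface_age_relax_yr: 0.05
  max_courant: 0.5
gas:
  piston_o2_m_yr: 1100.0
  piston_co2_m_yr: 1200.0
  atm_po2_atm: 0.21
biogeochem:
  stoich:
    r_c_p: 112.0
    r_n_p: 16.0
    r_o2_p: 169.6
    r_no3_p_denit: 119.68
    o2_denit_threshold: 5.0
  max_uptake_yr: 0.4
  k_po4: 0.5
  q10: 2.0
  t_ref_c: 16.0
  shoaling_per_k: 0.01
  remin_fractions:
    thermo: 0.62
    mid: 0.14
    deep: 0.15
    bottom: 0.09
  po4_init: 1.48
  no3_init: 23.0
  dic_init: 2260.0
  alk: 2371.0
  o2_init: 200.0
  metabolic_e0_ev: 0.4
diagnostics:
  hypoxic_mmol_m3: 70.0
  suboxic_mmol_m3: 5.0
  census_bin_width: 10.0
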