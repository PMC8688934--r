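# Baseline kinetic constants and whole-cell parameters.
#
# The six-state cotransporter topology follows the classical SGLT1 cycle
# (outward Na2 binding -> outward glucose binding -> translocation -> inner
# release -> empty-carrier return) and the GLUT2 law is a four-state
# alternating-conformation carrier. Their numerical rate constants, and the
# pump/channel/water parameters of the whole-cell model, are calibrated once
# so that the emergent behaviour reproduces the published operating point of
# the enterocyte model (equivalent Michaelis-Menten table of the transporter
# flux curves; steady-state ion concentrations, potentials and volumes of the
# three-compartment model). See the methods vignette for the calibration
# protocol. Units: mM^-1 s^-1 (mM^-2 s^-1 for Na+ binding), s^-1.

.SGLT1_DEFAULT <- list(
  k12 = 0.08,          # mM^-2 s^-1 outer 2Na+ binding (8e4 M^-2 s^-1)
  k21 = 500,           # s^-1
  k23 = 2.8555982,     # mM^-1 s^-1 outer glucose binding
  k32 = 128.4547834,   # s^-1
  k34 = 177.1556683,   # s^-1 loaded translocation
  k43 = 5.4074038,     # s^-1
  k45 = 63904.9954178, # s^-1 inner glucose release
  k54 = 2701.1636171,  # mM^-1 s^-1 inner glucose binding
  k56 = 2.5029768,     # s^-1 inner 2Na+ release
  k65 = 5e-05,         # mM^-2 s^-1
  k61 = 3.8760227      # s^-1 empty-carrier return (k16 derived from detailed balance)
)

.GLUT2_DEFAULT <- list(
  k_on_out = 1103.131501,   # mM^-1 s^-1 outward glucose binding
  k_off_out = 12426.856570, # s^-1  (outward Kd ~ 11.3 mM)
  k_on_in = 104.364031,     # mM^-1 s^-1 inward glucose binding
  k_off_in = 228.395823,    # s^-1  (inward Kd ~ 2.2 mM; asymmetric carrier)
  k_tl_oi = 145.655666,     # s^-1 loaded translocation out -> in
  k_tl_io = 1874.632520,    # s^-1 loaded translocation in -> out
  k_mt_io = 59.022823       # s^-1 empty return in -> out (k_mt_oi derived)
)
# Basolateral GLUT2: same four-state cycle, rescaled rates and a weaker
# inner-site affinity, calibrated against the whole-cell steady-state
# operating points (see the methods vignette).
.GLUT2_BL_DEFAULT <- list(
  k_on_out = 56.557124,   # mM^-1 s^-1
  k_off_out = 637.12011,  # s^-1
  k_on_in = 5.3507033,    # mM^-1 s^-1
  k_off_in = 124.27565,   # s^-1 (inner Kd ~ 23.2 mM)
  k_tl_oi = 7.4677094,    # s^-1
  k_tl_io = 96.111681,    # s^-1
  k_mt_io = 3.0260772     # s^-1
)

.PUMP_DEFAULT <- list(
  k_max = 170.49829,    # cycles/s
  km_na = 9.6433649,    # mM (intracellular Na+, Hill 3)
  km_k  = 1.5,       # mM (extracellular K+, Hill 2)
  n_copies = 5e6
)

# Whole-cell baseline: channel permeability-area products (m^3/s per cell),
# osmotic permeabilities (m^3/s per mOsm), impermeant osmolyte pool.
# "Calibrated" values are tuned to the model's published steady-state
# operating point; see vignette.
.CELL_DEFAULT <- list(
  p_ap_na  = 2.9461634e-18,
  p_ap_k   = 6.5392777e-19,
  p_ap_cl  = 1.2987537e-17,
  p_bl_na  = 1.1432932e-18,
  p_bl_k   = 2.9269041e-17,
  p_bl_cl  = 6.395654e-20,
  p_pc_na  = 7.6311506e-18,
  p_pc_k   = 1.5216459e-17,
  p_pc_cl  = 1.0027028e-18,
  lp_ap    = 1.6733394e-19,
  lp_bl    = 3.0000017e-20,
  lp_pc    = 1.0000405e-21,
  osmolyte_amount  = 6.988904e-14,  # mol (~70 mM at the 1e-15 m^3 reference volume)
  osmolyte_valence = -1.0731296   # mean valence (closes initial electroneutrality)
)
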