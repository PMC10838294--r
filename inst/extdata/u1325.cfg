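# hydrateRTM scenario configuration
name = u1325
# --- column geometry (m) and lithology ---
domain_length = 2.5
sand_thickness = 0.05
dz = 0.005
n_sand = 1000000000
n_mud = 1000000
poc_mud_wt = 0.5
porosity = 0.5
grain_density = 2.65
cell_decay_n_surface = 1000000000
cell_decay_efold = 1000
# --- kinetics (rate constants in s^-1 units; see rate_constants) ---
K_eh = 1.995262315e-13
K_fm = 1e-23
K_m = 1e-23
beta = 0.01
E0 = 0.5
lambda_half = 10000
epsilon = 0.0085
gamma_ch4 = 0.75
# --- transport (m^2/s) ---
D_hmw = 1e-10
D_lmw = 2.5e-10
D_enz = 2.5e-11
D_ch4 = 2.5e-10
# --- burial (mm/yr, m) ---
sed_rate = 0.19
d0 = 0
# --- methane solubility (mM, m) ---
sol_form = linear
c_ref = 32
d_ref = 0
d_scale = 2000
mud_multiplier = 1.006
bghsz_depth = 245
# --- discretization and outputs (yr, mM) ---
dt = 20
t_end = 1200000
series_dt = 2000
snapshot_times = 40000,80000,120000,160000,2e+05,240000,280000,320000,360000,4e+05,440000,480000,520000,560000,6e+05,640000,680000,720000,760000,8e+05,840000,880000,920000,960000,1e+06,1040000,1080000,1120000,1160000,1200000
c_h = 7623.443678
s_hfz = 0.01
s_top = 0.05
scheme = be
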