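# hydrateRTM scenario configuration
name = wr313h
# --- column geometry (m) and lithology ---
domain_length = 20
sand_thickness = 3
dz = 0.05
n_sand = 1000000000
n_mud = 1000000
poc_mud_wt = 0.5
porosity = 0.5
grain_density = 2.65
cell_decay_n_surface = 1000000000
cell_decay_efold = 200
# --- kinetics (rate constants in s^-1 units; see rate_constants) ---
K_eh = 2.511886432e-13
K_fm = 3.16227766e-22
K_m = 3.16227766e-22
beta = 0.01
E0 = 0.5
lambda_half = 10000
epsilon = 0.025
gamma_ch4 = 0.5
# --- transport (m^2/s) ---
D_hmw = 1e-10
D_lmw = 2.5e-10
D_enz = 2.5e-11
D_ch4 = 2.5e-10
# --- burial (mm/yr, m) ---
sed_rate = 1
d0 = 0
# --- methane solubility (mM, m) ---
sol_form = linear
c_ref = 45
d_ref = 0
d_scale = 700
mud_multiplier = 1.006
bghsz_depth = 900
# --- discretization and outputs (yr, mM) ---
dt = 10
t_end = 300000
series_dt = 1000
snapshot_times = 10000,20000,30000,40000,50000,60000,70000,80000,90000,1e+05,110000,120000,130000,140000,150000,160000,170000,180000,190000,2e+05,210000,220000,230000,240000,250000,260000,270000,280000,290000,3e+05
c_h = 7623.443678
s_hfz = 0.01
s_top = 0.05
scheme = cn
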