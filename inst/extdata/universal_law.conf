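# Published calibration of the surface law beta = alpha * S^(-nu),
# with beta in 1/meters and S the average unit surface in km2
# (non-dimensionalized by 1 km2). Fitted on 80 census case studies
# across Europe and the United States; shipped as data, not logic:
# every law computation in the package is tested against planted
# synthetic laws and does not depend on these values.
alpha_per_meter = 3.15e-4
nu = 0.177
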