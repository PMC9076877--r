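eye_id,expert,mspr_cat,cirrus_cat
eye01,progression,progression,stable
eye02,progression,progression,stable
eye03,progression,progression,progression
eye04,progression,progression,progression
eye05,progression,progression,progression
eye06,progression,progression,progression
eye07,progression,progression,progression
eye08,progression,progression,progression
eye09,progression,progression,progression
eye10,progression,progression,progression
eye11,progression,progression,progression
eye12,stable,progression,progression
eye13,stable,progression,progression
eye14,stable,progression,stable
eye15,stable,stable,stable
eye16,stable,stable,stable
eye17,stable,stable,stable
eye18,stable,stable,stable
eye19,stable,stable,stable
eye20,stable,stable,stable
eye21,stable,stable,stable
eye22,stable,stable,stable
eye23,regression,regression,progression
eye24,regression,regression,progression
eye25,regression,regression,progression
eye26,regression,regression,stable
eye27,regression,regression,stable
eye28,regression,regression,stable
eye29,regression,regression,regression
eye30,regression,regression,regression
eye31,regression,regression,regression
eye32,regression,regression,regression
eye33,regression,regression,regression
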