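{
  "label": "spA-spB",
  "parameters": {
    "ipc_method": "fraction",
    "bins": 4,
    "bootstrap_threshold": 90,
    "fdr": 0.01,
    "max_cluster_size": 200,
    "mww_mode": "cluster_means",
    "overlap_cutoff": 0.5,
    "segment_cutoff": 0.25
  },
  "counts": {
    "n_protein_records": 117,
    "n_genes": 100,
    "n_clusters": 20,
    "n_clusters_scored": 20,
    "n_multi_clusters": 16,
    "n_members_with_cno": 60,
    "n_members_with_cni": 60,
    "n_pair_values": 128,
    "n_pairs_undefined": 0
  },
  "pair_type_means": [
    {
      "pair_type": "i-cni",
      "mean_ipc": 0.381681,
      "mean_identity": 0.500781,
      "n_pairs": 20
    },
    {
      "pair_type": "i-i",
      "mean_ipc": 0.812897,
      "mean_identity": 0.892083,
      "n_pairs": 20
    },
    {
      "pair_type": "o-cno",
      "mean_ipc": 0.313916,
      "mean_identity": 0.502865,
      "n_pairs": 44
    },
    {
      "pair_type": "o-o",
      "mean_ipc": 0.494968,
      "mean_identity": 0.683049,
      "n_pairs": 44
    }
  ],
  "mww_tests": [
    {
      "comparison": "o-o vs o-cno",
      "n_1": 20,
      "n_2": 20,
      "p_value": 0.071471
    },
    {
      "comparison": "i-i vs i-cni",
      "n_1": 16,
      "n_2": 16,
      "p_value": 1.3e-05
    }
  ],
  "spearman": [
    {
      "pair_type": "i-cni",
      "rho": 0.024981,
      "p_value": 0.916739,
      "n": 20,
      "defined": true
    },
    {
      "pair_type": "i-i",
      "rho": -0.024847,
      "p_value": 0.917184,
      "n": 20,
      "defined": true
    },
    {
      "pair_type": "o-cno",
      "rho": -0.205535,
      "p_value": 0.180747,
      "n": 44,
      "defined": true
    },
    {
      "pair_type": "o-o",
      "rho": 0.226376,
      "p_value": 0.139504,
      "n": 44,
      "defined": true
    }
  ],
  "bins": {
    "ortholog": {
      "types": ["o-o", "o-cno"],
      "combined_boundaries": [0.568229, 0.589583, 0.61875],
      "ratios": [
        {
          "bin": 1,
          "mean_ipc_o-o": null,
          "mean_ipc_o-cno": 0.313916,
          "n_o-o": 0,
          "n_o-cno": 44,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 2,
          "mean_ipc_o-o": 0.5,
          "mean_ipc_o-cno": null,
          "n_o-o": 1,
          "n_o-cno": 0,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 3,
          "mean_ipc_o-o": 0.125,
          "mean_ipc_o-cno": null,
          "n_o-o": 2,
          "n_o-cno": 0,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 4,
          "mean_ipc_o-o": 0.512892,
          "mean_ipc_o-cno": null,
          "n_o-o": 41,
          "n_o-cno": 0,
          "log2_ratio": null,
          "defined": false
        }
      ]
    },
    "inparalog": {
      "types": ["i-i", "i-cni"],
      "combined_boundaries": [0.666667, 0.691667, 0.730208],
      "ratios": [
        {
          "bin": 1,
          "mean_ipc_i-i": null,
          "mean_ipc_i-cni": 0.381681,
          "n_i-i": 0,
          "n_i-cni": 20,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 2,
          "mean_ipc_i-i": null,
          "mean_ipc_i-cni": null,
          "n_i-i": 0,
          "n_i-cni": 0,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 3,
          "mean_ipc_i-i": null,
          "mean_ipc_i-cni": null,
          "n_i-i": 0,
          "n_i-cni": 0,
          "log2_ratio": null,
          "defined": false
        },
        {
          "bin": 4,
          "mean_ipc_i-i": 0.812897,
          "mean_ipc_i-cni": null,
          "n_i-i": 20,
          "n_i-cni": 0,
          "log2_ratio": null,
          "defined": false
        }
      ]
    }
  },
  "agreement_by_bootstrap": [
    {
      "n_high": 12,
      "fraction_high": 0.5,
      "n_low": 4,
      "fraction_low": 0.75,
      "n_unknown_bootstrap": 0
    }
  ],
  "enrichment": {
    "focal_species": "spA",
    "set_sizes": {
      "only_consistent": 11,
      "only_inconsistent": 13
    },
    "oversize_removed": [],
    "go_significant": [],
    "go_representatives": [],
    "pfam_significant": [],
    "property_tests": [
      {
        "property": "length_aa",
        "p_value": 1,
        "mean_fg": 120,
        "mean_bg": 120,
        "percent_difference": 0
      },
      {
        "property": "n_introns",
        "p_value": 0.442579,
        "mean_fg": 3.230769,
        "mean_bg": 3,
        "percent_difference": 7.692308
      },
      {
        "property": "n_pseudo_domains",
        "p_value": 0.310084,
        "mean_fg": 1.769231,
        "mean_bg": 2.090909,
        "percent_difference": -15.384615
      }
    ]
  }
}
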