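{
  "version": ["1"],
  "residues": ["ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "OTHER", "LIG"],
  "hybridizations": ["S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "UNSPECIFIED", "OTHER"],
  "node_names": ["atomic_number", "res_ALA", "res_ARG", "res_ASN", "res_ASP", "res_CYS", "res_GLN", "res_GLU", "res_GLY", "res_HIS", "res_ILE", "res_LEU", "res_LYS", "res_MET", "res_PHE", "res_PRO", "res_SER", "res_THR", "res_TRP", "res_TYR", "res_VAL", "res_OTHER", "res_LIG", "hyb_S", "hyb_SP", "hyb_SP2", "hyb_SP3", "hyb_SP3D", "hyb_SP3D2", "hyb_UNSPECIFIED", "hyb_OTHER", "degree", "is_aromatic", "n_hydrogens", "mass", "formal_charge", "gasteiger_charge", "x", "y", "z"],
  "edge_names": ["electrostatic_energy", "flag_halogen_bond", "flag_hydrogen_bond", "flag_hydrophobic", "flag_metal", "flag_pi_pi", "flag_t_stack", "flag_salt_bridge", "flag_cation_pi", "bond_type", "distance"],
  "ligand_descriptors": ["n_atoms", "n_heavy_atoms", "n_hydrogen_atoms", "n_bonds", "n_single_bonds", "n_double_bonds", "n_triple_bonds", "n_aromatic_bonds", "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_phosphorus", "n_fluorine", "n_chlorine", "n_bromine", "n_iodine", "n_halogen", "n_heteroatoms", "molecular_weight", "mean_atomic_mass", "heavy_atom_fraction", "heteroatom_fraction", "aromatic_atom_fraction", "fraction_sp3", "n_sp_atoms", "n_sp2_atoms", "n_sp3_atoms", "n_aromatic_atoms", "n_rings", "n_aromatic_rings", "n_aromatic_ring_atoms", "n_hbond_donors", "n_hbond_acceptors", "tpsa_estimate", "logp_estimate", "n_rotatable_bonds", "mean_bond_length", "total_formal_charge", "n_positive_atoms", "n_negative_atoms", "mean_partial_charge", "sd_partial_charge", "min_partial_charge", "max_partial_charge", "sum_abs_partial_charge", "mean_degree", "max_degree", "n_degree_1", "n_degree_2", "n_degree_3", "n_degree_4plus", "zagreb_index", "chi0_connectivity", "chi1_connectivity", "radius_of_gyration", "max_interatomic_distance", "mean_interatomic_distance", "span_x", "span_y", "span_z", "asphericity", "acylindricity", "surface_area_estimate", "polar_surface_area_estimate", "apolar_surface_area_estimate", "polar_surface_fraction", "mean_vdw_radius", "vdw_volume_estimate", "fraction_carbon", "fraction_nitrogen", "fraction_oxygen", "fraction_sulfur", "n_fragments", "n_ring_bonds", "n_bridge_bonds", "graph_diameter", "mean_graph_distance", "charge_bin_01", "charge_bin_02", "charge_bin_03", "charge_bin_04", "charge_bin_05", "charge_bin_06", "charge_bin_07", "charge_bin_08", "charge_bin_09", "charge_bin_10"],
  "pocket_descriptors": ["n_res_ALA", "n_res_ARG", "n_res_ASN", "n_res_ASP", "n_res_CYS", "n_res_GLN", "n_res_GLU", "n_res_GLY", "n_res_HIS", "n_res_ILE", "n_res_LEU", "n_res_LYS", "n_res_MET", "n_res_PHE", "n_res_PRO", "n_res_SER", "n_res_THR", "n_res_TRP", "n_res_TYR", "n_res_VAL", "n_res_other", "n_residues", "n_chains", "n_atoms", "n_heavy_atoms", "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_metal", "n_other_elements", "n_hydrophobic_residues", "n_polar_residues", "n_positive_residues", "n_negative_residues", "n_aromatic_residues", "mean_residue_size", "total_formal_charge", "mean_partial_charge", "sd_partial_charge", "min_partial_charge", "max_partial_charge", "sum_abs_partial_charge", "n_hbond_donors", "n_hbond_acceptors", "polar_atom_fraction", "n_aromatic_rings", "n_aromatic_atoms", "kd_hydrophobicity_mean", "kd_hydrophobicity_total", "radius_of_gyration", "span_x", "span_y", "span_z", "max_interatomic_distance", "mean_interatomic_distance", "asphericity", "acylindricity", "mean_vdw_radius", "vdw_volume_estimate", "surface_area_estimate", "polar_surface_area_estimate", "apolar_surface_area_estimate", "polar_surface_fraction", "charge_bin_01", "charge_bin_02", "charge_bin_03", "charge_bin_04", "charge_bin_05", "charge_bin_06", "charge_bin_07", "charge_bin_08", "charge_bin_09", "charge_bin_10"]
}
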