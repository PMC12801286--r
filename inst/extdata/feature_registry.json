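{
  "registry_version": "1.0",
  "length": 226,
  "names": ["dist_le0_agg_count", "dist_le0_agg_total_area", "dist_le0_agg_mean_area", "dist_le0_fl1_count", "dist_le0_fl1_total_area", "dist_le0_fl1_mean_area", "dist_le0_fl2_count", "dist_le0_fl2_total_area", "dist_le0_fl2_mean_area", "dist_0_04_agg_count", "dist_0_04_agg_total_area", "dist_0_04_agg_mean_area", "dist_0_04_fl1_count", "dist_0_04_fl1_total_area", "dist_0_04_fl1_mean_area", "dist_0_04_fl2_count", "dist_0_04_fl2_total_area", "dist_0_04_fl2_mean_area", "dist_04_10_agg_count", "dist_04_10_agg_total_area", "dist_04_10_agg_mean_area", "dist_04_10_fl1_count", "dist_04_10_fl1_total_area", "dist_04_10_fl1_mean_area", "dist_04_10_fl2_count", "dist_04_10_fl2_total_area", "dist_04_10_fl2_mean_area", "dist_10_22_agg_count", "dist_10_22_agg_total_area", "dist_10_22_agg_mean_area", "dist_10_22_fl1_count", "dist_10_22_fl1_total_area", "dist_10_22_fl1_mean_area", "dist_10_22_fl2_count", "dist_10_22_fl2_total_area", "dist_10_22_fl2_mean_area", "dist_22_45_agg_count", "dist_22_45_agg_total_area", "dist_22_45_agg_mean_area", "dist_22_45_fl1_count", "dist_22_45_fl1_total_area", "dist_22_45_fl1_mean_area", "dist_22_45_fl2_count", "dist_22_45_fl2_total_area", "dist_22_45_fl2_mean_area", "dist_45_64_agg_count", "dist_45_64_agg_total_area", "dist_45_64_agg_mean_area", "dist_45_64_fl1_count", "dist_45_64_fl1_total_area", "dist_45_64_fl1_mean_area", "dist_45_64_fl2_count", "dist_45_64_fl2_total_area", "dist_45_64_fl2_mean_area", "dist_gt64_agg_count", "dist_gt64_agg_total_area", "dist_gt64_agg_mean_area", "dist_gt64_fl1_count", "dist_gt64_fl1_total_area", "dist_gt64_fl1_mean_area", "dist_gt64_fl2_count", "dist_gt64_fl2_total_area", "dist_gt64_fl2_mean_area", "area_0_003_agg_count", "area_0_003_agg_total_area", "area_0_003_agg_mean_area", "area_0_003_fl1_count", "area_0_003_fl1_total_area", "area_0_003_fl1_mean_area", "area_0_003_fl2_count", "area_0_003_fl2_total_area", "area_0_003_fl2_mean_area", "area_003_005_agg_count", "area_003_005_agg_total_area", "area_003_005_agg_mean_area", "area_003_005_fl1_count", "area_003_005_fl1_total_area", "area_003_005_fl1_mean_area", "area_003_005_fl2_count", "area_003_005_fl2_total_area", "area_003_005_fl2_mean_area", "area_005_007_agg_count", "area_005_007_agg_total_area", "area_005_007_agg_mean_area", "area_005_007_fl1_count", "area_005_007_fl1_total_area", "area_005_007_fl1_mean_area", "area_005_007_fl2_count", "area_005_007_fl2_total_area", "area_005_007_fl2_mean_area", "area_007_010_agg_count", "area_007_010_agg_total_area", "area_007_010_agg_mean_area", "area_007_010_fl1_count", "area_007_010_fl1_total_area", "area_007_010_fl1_mean_area", "area_007_010_fl2_count", "area_007_010_fl2_total_area", "area_007_010_fl2_mean_area", "area_010_015_agg_count", "area_010_015_agg_total_area", "area_010_015_agg_mean_area", "area_010_015_fl1_count", "area_010_015_fl1_total_area", "area_010_015_fl1_mean_area", "area_010_015_fl2_count", "area_010_015_fl2_total_area", "area_010_015_fl2_mean_area", "area_015_028_agg_count", "area_015_028_agg_total_area", "area_015_028_agg_mean_area", "area_015_028_fl1_count", "area_015_028_fl1_total_area", "area_015_028_fl1_mean_area", "area_015_028_fl2_count", "area_015_028_fl2_total_area", "area_015_028_fl2_mean_area", "area_gt028_agg_count", "area_gt028_agg_total_area", "area_gt028_agg_mean_area", "area_gt028_fl1_count", "area_gt028_fl1_total_area", "area_gt028_fl1_mean_area", "area_gt028_fl2_count", "area_gt028_fl2_total_area", "area_gt028_fl2_mean_area", "joint_le0_0_003_count", "joint_le0_0_003_total_area", "joint_le0_003_005_count", "joint_le0_003_005_total_area", "joint_le0_005_007_count", "joint_le0_005_007_total_area", "joint_le0_007_010_count", "joint_le0_007_010_total_area", "joint_le0_010_015_count", "joint_le0_010_015_total_area", "joint_le0_015_028_count", "joint_le0_015_028_total_area", "joint_le0_gt028_count", "joint_le0_gt028_total_area", "joint_0_04_0_003_count", "joint_0_04_0_003_total_area", "joint_0_04_003_005_count", "joint_0_04_003_005_total_area", "joint_0_04_005_007_count", "joint_0_04_005_007_total_area", "joint_0_04_007_010_count", "joint_0_04_007_010_total_area", "joint_0_04_010_015_count", "joint_0_04_010_015_total_area", "joint_0_04_015_028_count", "joint_0_04_015_028_total_area", "joint_0_04_gt028_count", "joint_0_04_gt028_total_area", "joint_04_10_0_003_count", "joint_04_10_0_003_total_area", "joint_04_10_003_005_count", "joint_04_10_003_005_total_area", "joint_04_10_005_007_count", "joint_04_10_005_007_total_area", "joint_04_10_007_010_count", "joint_04_10_007_010_total_area", "joint_04_10_010_015_count", "joint_04_10_010_015_total_area", "joint_04_10_015_028_count", "joint_04_10_015_028_total_area", "joint_04_10_gt028_count", "joint_04_10_gt028_total_area", "joint_10_22_0_003_count", "joint_10_22_0_003_total_area", "joint_10_22_003_005_count", "joint_10_22_003_005_total_area", "joint_10_22_005_007_count", "joint_10_22_005_007_total_area", "joint_10_22_007_010_count", "joint_10_22_007_010_total_area", "joint_10_22_010_015_count", "joint_10_22_010_015_total_area", "joint_10_22_015_028_count", "joint_10_22_015_028_total_area", "joint_10_22_gt028_count", "joint_10_22_gt028_total_area", "joint_22_45_0_003_count", "joint_22_45_0_003_total_area", "joint_22_45_003_005_count", "joint_22_45_003_005_total_area", "joint_22_45_005_007_count", "joint_22_45_005_007_total_area", "joint_22_45_007_010_count", "joint_22_45_007_010_total_area", "joint_22_45_010_015_count", "joint_22_45_010_015_total_area", "joint_22_45_015_028_count", "joint_22_45_015_028_total_area", "joint_22_45_gt028_count", "joint_22_45_gt028_total_area", "joint_45_64_0_003_count", "joint_45_64_0_003_total_area", "joint_45_64_003_005_count", "joint_45_64_003_005_total_area", "joint_45_64_005_007_count", "joint_45_64_005_007_total_area", "joint_45_64_007_010_count", "joint_45_64_007_010_total_area", "joint_45_64_010_015_count", "joint_45_64_010_015_total_area", "joint_45_64_015_028_count", "joint_45_64_015_028_total_area", "joint_45_64_gt028_count", "joint_45_64_gt028_total_area", "joint_gt64_0_003_count", "joint_gt64_0_003_total_area", "joint_gt64_003_005_count", "joint_gt64_003_005_total_area", "joint_gt64_005_007_count", "joint_gt64_005_007_total_area", "joint_gt64_007_010_count", "joint_gt64_007_010_total_area", "joint_gt64_010_015_count", "joint_gt64_010_015_total_area", "joint_gt64_015_028_count", "joint_gt64_015_028_total_area", "joint_gt64_gt028_count", "joint_gt64_gt028_total_area", "tumor_total_area_mm2", "tumor_mean_area_per_slide_mm2"]
}
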