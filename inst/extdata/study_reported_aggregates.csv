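quantity,value,tol
rmse_px_lv_heatmap,5.09,0.005
rmse_px_a_heatmap,6.56,0.005
rmse_px_rv_heatmap,6.40,0.005
rmse_px_overall_heatmap,6.02,0.005
rmse_px_delta_direct,2.54,0.01
anova_rmse_px_F,12.10,0.005
anova_rmse_px_p,0.0038,0.00005
g_rmse_px_heatmap_direct,2.76,0.005
g_rmse_px_heatmap_segmentation,1.20,0.005
g_rmse_px_direct_segmentation,1.08,0.005
holm_rmse_px_heatmap_direct,0.0227,0.00005
holm_rmse_px_heatmap_segmentation,0.0853,0.00005
holm_rmse_px_direct_segmentation,0.0853,0.00005
aga_mae_heatmap,5.87,0.005
aga_mae_direct,10.36,0.005
aga_mae_segmentation,6.23,0.005
aga_rmse_heatmap,13.54,0.005
aga_rmse_direct,15.87,0.005
aga_rmse_segmentation,8.95,0.005
anova_aga_mae_F,9.64,0.005
anova_aga_mae_p,0.0074,0.00005
anova_aga_mae_eta_sq,0.632,0.0005
g_aga_mae_heatmap_direct,2.25,0.005
g_aga_mae_heatmap_segmentation,0.18,0.005
holm_aga_mae_heatmap_direct,0.0247,0.00005
holm_aga_mae_heatmap_segmentation,0.7631,0.00005
anova_aga_rmse_F,4.23,0.005
anova_aga_rmse_p,0.0557,0.00005
anova_aga_rmse_eta_sq,0.399,0.0005
g_aga_rmse_direct_segmentation,2.77,0.005
g_aga_rmse_heatmap_segmentation,0.91,0.005
holm_aga_rmse_direct_segmentation,0.0437,0.00005
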