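table,fold,method,metric,keypoint,mean,sd
1,0,heatmap,rmse_px,LV,5.45,13.89
1,0,heatmap,rmse_px,A,8.45,19.38
1,0,heatmap,rmse_px,RV,5.60,11.57
1,0,direct,rmse_px,LV,8.49,6.15
1,0,direct,rmse_px,A,8.66,6.82
1,0,direct,rmse_px,RV,7.74,4.70
1,0,segmentation,rmse_px,LV,6.51,8.46
1,0,segmentation,rmse_px,A,7.08,6.07
1,0,segmentation,rmse_px,RV,6.55,7.36
1,1,heatmap,rmse_px,LV,5.72,13.87
1,1,heatmap,rmse_px,A,5.79,15.13
1,1,heatmap,rmse_px,RV,6.66,16.41
1,1,direct,rmse_px,LV,9.38,7.60
1,1,direct,rmse_px,A,8.44,8.05
1,1,direct,rmse_px,RV,10.12,10.43
1,1,segmentation,rmse_px,LV,8.75,11.56
1,1,segmentation,rmse_px,A,10.65,9.91
1,1,segmentation,rmse_px,RV,9.03,12.54
1,2,heatmap,rmse_px,LV,3.47,3.65
1,2,heatmap,rmse_px,A,5.03,12.46
1,2,heatmap,rmse_px,RV,5.17,12.31
1,2,direct,rmse_px,LV,9.03,7.44
1,2,direct,rmse_px,A,8.96,8.49
1,2,direct,rmse_px,RV,7.75,6.49
1,2,segmentation,rmse_px,LV,6.92,8.95
1,2,segmentation,rmse_px,A,6.45,6.32
1,2,segmentation,rmse_px,RV,6.68,9.07
1,3,heatmap,rmse_px,LV,4.90,13.73
1,3,heatmap,rmse_px,A,4.89,10.68
1,3,heatmap,rmse_px,RV,6.89,18.49
1,3,direct,rmse_px,LV,7.47,6.27
1,3,direct,rmse_px,A,8.66,6.42
1,3,direct,rmse_px,RV,7.83,6.24
1,3,segmentation,rmse_px,LV,7.15,10.64
1,3,segmentation,rmse_px,A,7.72,7.44
1,3,segmentation,rmse_px,RV,6.89,9.39
1,4,heatmap,rmse_px,LV,5.92,12.98
1,4,heatmap,rmse_px,A,8.64,18.81
1,4,heatmap,rmse_px,RV,7.70,13.53
1,4,direct,rmse_px,LV,7.66,6.91
1,4,direct,rmse_px,A,9.74,8.26
1,4,direct,rmse_px,RV,8.36,8.03
1,4,segmentation,rmse_px,LV,6.51,8.98
1,4,segmentation,rmse_px,A,8.45,10.57
1,4,segmentation,rmse_px,RV,7.04,8.91
2,0,heatmap,aga_mae_deg,,6.39,1.58
2,0,heatmap,aga_rmse_deg,,15.01,5.63
2,0,direct,aga_mae_deg,,8.74,1.25
2,0,direct,aga_rmse_deg,,13.17,1.56
2,0,segmentation,aga_mae_deg,,8.88,2.56
2,0,segmentation,aga_rmse_deg,,11.84,2.41
2,1,heatmap,aga_mae_deg,,6.54,1.44
2,1,heatmap,aga_rmse_deg,,14.62,3.42
2,1,direct,aga_mae_deg,,13.03,2.35
2,1,direct,aga_rmse_deg,,18.59,2.99
2,1,segmentation,aga_mae_deg,,5.13,1.00
2,1,segmentation,aga_rmse_deg,,6.87,1.80
2,2,heatmap,aga_mae_deg,,4.40,1.65
2,2,heatmap,aga_rmse_deg,,9.30,2.19
2,2,direct,aga_mae_deg,,9.94,1.56
2,2,direct,aga_rmse_deg,,14.04,2.29
2,2,segmentation,aga_mae_deg,,4.99,0.90
2,2,segmentation,aga_rmse_deg,,6.46,0.86
2,3,heatmap,aga_mae_deg,,3.52,0.52
2,3,heatmap,aga_rmse_deg,,6.53,1.32
2,3,direct,aga_mae_deg,,9.45,1.73
2,3,direct,aga_rmse_deg,,17.32,3.88
2,3,segmentation,aga_mae_deg,,6.53,0.79
2,3,segmentation,aga_rmse_deg,,9.44,1.94
2,4,heatmap,aga_mae_deg,,8.48,2.95
2,4,heatmap,aga_rmse_deg,,22.25,8.10
2,4,direct,aga_mae_deg,,10.66,1.52
2,4,direct,aga_rmse_deg,,16.22,3.48
2,4,segmentation,aga_mae_deg,,5.61,1.55
2,4,segmentation,aga_rmse_deg,,10.12,3.30
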